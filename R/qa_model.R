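# Linear support-vector regression mapping feature vectors to local
# S-scores. Hyperparameters (cost C and the epsilon tube width) are chosen
# by grid search scored with target-level five-fold cross-validated Pearson
# correlation: all residues of one target stay in one fold, and a single
# (C, epsilon) pair is selected for all folds jointly. Feature
# standardization is fit on the training folds only during CV and stored in
# the final model.

.fingerprint <- function(names) {
  # polynomial rolling hash over the concatenated layout names; stable
  # across sessions and platforms
  h <- 17
  for (b in utf8ToInt(paste(names, collapse = "|")))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.fit_scaling <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.apply_scaling <- function(x, sc)
  sweep(sweep(x, 2, sc$center), 2, sc$scale, "/")

.fit_svr <- function(x, y, C, eps) {
  fit <- e1071::svm(x, y, type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = eps, scale = FALSE)
  list(w = as.vector(t(fit$coefs) %*% fit$SV), b = -fit$rho)
}

.target_folds <- function(targets, n_folds, seed) {
  u <- unique(targets)
  if (length(u) < 2) stop("need at least 2 targets for target-level folds")
  k <- min(n_folds, length(u))
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(u))), u)
  unname(fold_of[targets])
}

#' Train the local-quality regressor
#'
#' Fits linear epsilon-SVR models over a (C, epsilon) grid, scores each pair
#' by mean target-level five-fold cross-validated Pearson correlation
#' between predicted and true local S-scores, and refits the best pair on
#' all data.
#'
#' @param features numeric matrix (rows = residues) with column names giving
#'   the feature layout.
#' @param s true local S-scores in [0,1], one per row.
#' @param targets target identifier per row; folds are split by target.
#' @param C_grid candidate SVR cost values.
#' @param eps_grid candidate epsilon tube widths.
#' @param n_folds number of cross-validation folds.
#' @param seed seed controlling fold assignment.
#' @return a \code{proq_model}: list with \code{weights}, \code{bias},
#'   \code{center}/\code{scale} standardization, chosen \code{C} and
#'   \code{epsilon}, the CV report (\code{cv}, one row per grid point) and
#'   the feature-layout \code{fingerprint}.
#' @export
proq_train <- function(features, s, targets,
                       C_grid = c(0.01, 0.1, 1, 10),
                       eps_grid = c(0.05, 0.1, 0.2),
                       n_folds = 5, seed = 1) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) {
    bad <- colnames(features)[apply(features, 2, function(c) any(!is.finite(c)))]
    stop("non-finite feature values in: ", paste(bad, collapse = ", "))
  }
  stopifnot(length(s) == nrow(features), length(targets) == nrow(features),
            all(s >= 0 & s <= 1))
  fold <- .target_folds(targets, n_folds, seed)
  grid <- expand.grid(C = C_grid, eps = eps_grid)
  grid$cv_r <- NA_real_
  for (g in seq_len(nrow(grid))) {
    rs <- vapply(sort(unique(fold)), function(f) {
      tr <- fold != f
      sc <- .fit_scaling(features[tr, , drop = FALSE])
      m <- .fit_svr(.apply_scaling(features[tr, , drop = FALSE], sc), s[tr],
                    grid$C[g], grid$eps[g])
      pred <- .apply_scaling(features[!tr, , drop = FALSE], sc) %*% m$w + m$b
      if (stats::sd(pred) == 0 || stats::sd(s[!tr]) == 0) return(NA_real_)
      stats::cor(as.vector(pred), s[!tr])
    }, numeric(1))
    grid$cv_r[g] <- mean(rs, na.rm = TRUE)
  }
  best <- which.max(grid$cv_r)
  sc <- .fit_scaling(features)
  m <- .fit_svr(.apply_scaling(features, sc), s, grid$C[best], grid$eps[best])
  structure(list(weights = stats::setNames(m$w, colnames(features)),
                 bias = m$b, center = sc$center, scale = sc$scale,
                 C = grid$C[best], epsilon = grid$eps[best], cv = grid,
                 fingerprint = .fingerprint(colnames(features)),
                 feature_names = colnames(features)),
            class = "proq_model")
}

#' @export
print.proq_model <- function(x, ...) {
  cat(sprintf("<proq_model> %d features, C=%g eps=%g, CV R=%.3f\n",
              length(x$weights), x$C, x$epsilon, max(x$cv$cv_r)))
  invisible(x)
}

#' Predict local S-scores from feature vectors
#'
#' Raw linear SVR output on standardized features, clamped to [0,1].
#'
#' @param model a \code{proq_model}.
#' @param features numeric matrix whose columns match the training layout.
#' @return numeric vector of predicted per-residue S-scores in [0,1].
#' @export
predict_local <- function(model, features) {
  features <- as.matrix(features)
  if (!identical(.fingerprint(colnames(features)), model$fingerprint))
    stop("feature layout fingerprint mismatch: model was trained on a ",
         "different layout")
  raw <- .apply_scaling(features, model) %*% model$weights + model$bias
  pmin(1, pmax(0, as.vector(raw)))
}

#' @export
predict.proq_model <- function(object, newdata, ...) predict_local(object, newdata)

#' Global model quality from local scores
#'
#' The sum of the per-residue predicted S-scores divided by the target
#' sequence length; unmodeled target residues contribute zero, so partial
#' models are penalized.
#'
#' @param local_s per-residue predicted S-scores of the modeled residues.
#' @param target_length target sequence length (>= number of scores).
#' @return global quality in [0,1].
#' @export
predict_global <- function(local_s, target_length) {
  if (target_length < length(local_s))
    stop("target_length smaller than the number of local scores")
  sum(pmin(1, pmax(0, local_s))) / target_length
}

#' Save / load a trained model as versioned JSON
#'
#' @param model a \code{proq_model}.
#' @param path JSON file.
#' @return \code{load_model} returns the \code{proq_model}.
#' @export
save_model <- function(model, path) {
  obj <- unclass(model)
  obj$format_version <- 1L
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version))
    stop("not a serialized model: ", path)
  obj$format_version <- NULL
  obj$weights <- stats::setNames(as.numeric(obj$weights), obj$feature_names)
  obj$center <- stats::setNames(as.numeric(obj$center), obj$feature_names)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$feature_names)
  structure(obj, class = "proq_model")
}
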