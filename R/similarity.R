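# Structural similarity: the per-residue S-score target function, its
# inverse distance form, least-squares superposition and the seed-and-extend
# search that maximizes the summed S-score (MaxSub-style), plus GDT_TS.

#' Per-residue S-score from a distance deviation
#'
#' S = 1 / (1 + (d/d0)^2): 1 for a perfectly placed residue, 0.5 at the
#' distance threshold d0, approaching 0 as the deviation grows.
#'
#' @param d distance(s) between model and reference residue, Angstrom.
#' @param d0 distance threshold (Angstrom) at which the score is 0.5.
#' @return score(s) in (0,1].
#' @export
s_score <- function(d, d0 = 3) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be non-negative")
  if (d0 <= 0) stop("d0 must be positive")
  1 / (1 + (d / d0)^2)
}

#' Distance deviation corresponding to an S-score
#'
#' Exact inverse of \code{\link{s_score}}: d = d0 * sqrt(1/S - 1).
#'
#' @param s score(s) in (0,1].
#' @param d0 distance threshold, Angstrom.
#' @return distance(s) in Angstrom.
#' @export
s_to_distance <- function(s, d0 = 3) {
  if (any(s <= 0 | s > 1, na.rm = TRUE)) stop("s must lie in (0,1]")
  d0 * sqrt(1 / s - 1)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of
#' \code{model_coords[subset,]} onto \code{ref_coords[subset,]}.
#'
#' @param model_coords,ref_coords n x 3 matrices of matched coordinates.
#' @param subset indices of rows used for the fit (default all).
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3), \code{rmsd} over the subset and \code{subset}. The fitted
#'   model coordinate is \code{rotation \%*\% x + translation}.
#' @export
kabsch <- function(model_coords, ref_coords, subset = NULL) {
  P <- as.matrix(model_coords); Q <- as.matrix(ref_coords)
  if (is.null(subset)) subset <- seq_len(nrow(P))
  if (length(subset) < 3) stop("need at least 3 matched points")
  P <- P[subset, , drop = FALSE]; Q <- Q[subset, , drop = FALSE]
  if (anyNA(P) || anyNA(Q)) stop("NA coordinates in superposition subset")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  if (dsign == 0) stop("degenerate geometry: singular cross-covariance")
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  tr <- qc - as.vector(R %*% pc)
  fitted <- t(R %*% t(P)) + matrix(tr, nrow(P), 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums((fitted - Q)^2))), subset = subset)
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix.
#' @param sup result of \code{\link{kabsch}}.
#' @return transformed n x 3 matrix.
#' @export
transform_coords <- function(coords, sup) {
  t(sup$rotation %*% t(as.matrix(coords))) +
    matrix(sup$translation, nrow(coords), 3, byrow = TRUE)
}

# seed-and-extend search over CA coordinate sets. Returns the candidate
# (included-set superposition) maximizing `objective(d)` where d are the
# per-residue distances of all matched residues.
.seed_extend <- function(P, Q, incl_thresh, objective,
                         seed_len = 7, max_iter = 10) {
  n <- nrow(P)
  seeds <- list(seq_len(n))
  if (n >= seed_len)
    seeds <- c(seeds, lapply(seq_len(n - seed_len + 1),
                             function(i) i:(i + seed_len - 1)))
  best <- NULL; best_val <- -Inf
  for (seed in seeds) {
    set <- seed
    for (iter in seq_len(max_iter)) {
      sup <- tryCatch(kabsch(P, Q, set), error = function(e) NULL)
      if (is.null(sup)) break
      d <- sqrt(rowSums((transform_coords(P, sup) - Q)^2))
      val <- objective(d)
      if (val > best_val) {
        best_val <- val
        best <- list(sup = sup, d = d)
      }
      new_set <- which(d <= incl_thresh)
      if (length(new_set) < 3 || identical(new_set, set)) break
      set <- new_set
    }
  }
  if (is.null(best)) stop("superposition failed: fewer than 3 usable residues")
  best
}

.matched_positions <- function(model, ref) {
  mc <- ca_coords(model); rc <- ca_coords(ref)
  common <- intersect(model$target_pos, ref$target_pos)
  mi <- match(common, model$target_pos); ri <- match(common, ref$target_pos)
  ok <- stats::complete.cases(mc[mi, , drop = FALSE]) &
        stats::complete.cases(rc[ri, , drop = FALSE])
  list(mi = mi[ok], ri = ri[ok], mc = mc, rc = rc)
}

#' Superposition maximizing the summed per-residue S-score
#'
#' MaxSub-style search for the rigid superposition of a model onto a
#' reference that maximizes the sum of S-scores over the whole model: every
#' contiguous 7-residue window seeds a superposition that is iteratively
#' extended with all residues within an inclusion threshold until a fixed
#' point; the all-residue least-squares fit is always among the candidates,
#' so the result can never score below it.
#'
#' @param model,ref \code{protein_model}s mapped to the same target.
#' @param d0 S-score distance threshold (Angstrom).
#' @param seed_len seed window length.
#' @param incl_factor inclusion threshold during extension, as a multiple of
#'   \code{d0}.
#' @param max_iter maximum extension iterations per seed.
#' @return list with \code{superposition}, \code{sum_s}, and \code{local}: a
#'   data.frame over target positions 1..target_length with per-residue
#'   distance \code{d} (NA where unmodeled in either structure) and score
#'   \code{s} (0 where unmodeled).
#' @export
optimal_s_superposition <- function(model, ref, d0 = 3, seed_len = 7,
                                    incl_factor = 3.5, max_iter = 10) {
  m <- .matched_positions(model, ref)
  if (length(m$mi) < 3) stop("fewer than 3 matched residues with CA atoms")
  P <- m$mc[m$mi, , drop = FALSE]; Q <- m$rc[m$ri, , drop = FALSE]
  sl <- if (length(m$mi) >= seed_len) seed_len else length(m$mi)
  best <- .seed_extend(P, Q, incl_thresh = incl_factor * d0,
                       objective = function(d) sum(s_score(d, d0)),
                       seed_len = sl, max_iter = max_iter)
  tl <- max(model$target_length, ref$target_length)
  d <- rep(NA_real_, tl); s <- numeric(tl)
  pos <- model$target_pos[m$mi]
  d[pos] <- best$d
  s[pos] <- s_score(best$d, d0)
  list(superposition = best$sup, sum_s = sum(s),
       local = data.frame(target_pos = seq_len(tl), d = d, s = s))
}

#' GDT_TS global similarity score
#'
#' Mean over the 1, 2, 4 and 8 Angstrom thresholds of the maximal fraction
#' of matched C-alpha atoms that can be superposed within the threshold,
#' found by the same seed-and-extend heuristic per threshold, reported on a
#' 0-100 scale. The fraction denominator is the number of reference
#' residues.
#'
#' @param model,ref \code{protein_model}s mapped to the same target.
#' @param thresholds distance thresholds in Angstrom.
#' @return GDT_TS in [0, 100].
#' @export
gdt_ts <- function(model, ref, thresholds = c(1, 2, 4, 8)) {
  m <- .matched_positions(model, ref)
  if (length(m$mi) < 3) stop("fewer than 3 matched residues with CA atoms")
  P <- m$mc[m$mi, , drop = FALSE]; Q <- m$rc[m$ri, , drop = FALSE]
  n_ref <- n_residues(ref)
  fr <- vapply(thresholds, function(thr) {
    best <- .seed_extend(P, Q, incl_thresh = thr,
                         objective = function(d) sum(d <= thr))
    sum(best$d <= thr) / n_ref
  }, numeric(1))
  100 * mean(fr)
}
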