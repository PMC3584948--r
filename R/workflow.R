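# Workflow layer: run configuration with the published defaults, and the
# orchestration functions behind the command-line interface (score a model
# directory, train, evaluate, consensus-score). Machine-readable outputs
# embed a hash of the configuration so reruns are verifiable.

#' Run configuration
#'
#' Collects every tunable constant with its default: the S-score threshold
#' d0 = 3 A, atom/residue contact cutoffs of 4 A and 6 A with their sequence
#' separation rules, window sizes 21/21/5/21/13/3, the 25% burial threshold,
#' the consensus mixing weight k = 0.8, SVR grids, SASA resolution and the
#' seed.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated named list of class \code{proq_config}.
#' @export
proq_config <- function(...) {
  cfg <- list(
    d0 = 3, atom_cutoff = 4, atom_min_sep = 2,
    res_cutoff = 6, res_min_sep = 6,
    window = 21, window_ss = 21, window_ss5 = 5,
    window_surf = 21, window_area = 13, window_ipp = 3,
    buried_cut = 0.25, k = 0.8,
    C_grid = c(0.01, 0.1, 1, 10), eps_grid = c(0.05, 0.1, 0.2),
    sasa_points = 960, probe = 1.4, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (f in c("d0", "atom_cutoff", "res_cutoff", "probe"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  for (f in c("window", "window_ss", "window_ss5", "window_surf",
              "window_area", "window_ipp"))
    if (cfg[[f]] %% 2 != 1) stop(f, " must be odd")
  if (cfg$k < 0 || cfg$k > 1) stop("k must lie in [0,1]")
  structure(cfg, class = c("proq_config", "list"))
}

#' Hash of a configuration (embedded in all outputs)
#' @param config a \code{proq_config}.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(config) {
  .fingerprint(vapply(unclass(config),
                      function(v) paste(format(v, digits = 12), collapse = ","),
                      character(1)))
}

#' Write a quality-assessment record for one model
#'
#' Plain-text format: comment lines with the config hash, then one line
#' "<model_id> <global score> <d_1> <d_2> ..." with per-residue predicted
#' distance deviations (via \code{\link{s_to_distance}}; "X" where the
#' residue is not modeled).
#'
#' @param path output file (appended to if it exists).
#' @param model_id identifier.
#' @param global global score.
#' @param local_s per-residue predicted S-scores over target positions
#'   (NA where unmodeled).
#' @param config a \code{proq_config}.
#' @param d0 distance threshold used for the conversion.
#' @export
write_qa_record <- function(path, model_id, global, local_s,
                            config = proq_config(), d0 = config$d0) {
  dists <- ifelse(is.na(local_s), "X",
                  sprintf("%.2f", s_to_distance(pmax(pmin(local_s, 1), 1e-3),
                                                d0)))
  hdr <- if (!file.exists(path))
    c("# proqr QA", paste0("# config ", config_hash(config))) else character()
  cat(c(hdr, paste(model_id, sprintf("%.4f", global),
                   paste(dists, collapse = " "))),
      sep = "\n", file = path, append = file.exists(path))
  invisible(path)
}

.read_seq_inputs <- function(pssm, ss2, acc) {
  for (nm in c("pssm", "ss2", "acc")) {
    p <- get(nm)
    if (is.null(p) || !file.exists(p))
      stop("missing sequence-input file for --", nm,
           if (!is.null(p)) paste0(": ", p) else "")
  }
  list(profile = read_pssm(pssm), ss_pred = read_ss2(ss2),
       exp_pred = read_exposure_prediction(acc))
}

#' Score protein models with a trained regressor
#'
#' For each model: feature extraction, local prediction, global aggregation,
#' and one QA record in the output file.
#'
#' @param model_paths PDB files of the models (one target).
#' @param model_file path of a serialized \code{proq_model} (JSON), or the
#'   object itself.
#' @param pssm,ss2,acc sequence-input files for the target.
#' @param out output QA file (overwritten).
#' @param config a \code{proq_config}.
#' @param target_length optional target length; defaults to the profile
#'   length.
#' @return invisibly, a data.frame (model_id, global).
#' @export
run_score <- function(model_paths, model_file, pssm, ss2, acc, out,
                      config = proq_config(), target_length = NULL) {
  if (!length(model_paths)) stop("no model PDB files given")
  si <- .read_seq_inputs(pssm, ss2, acc)
  qa <- if (inherits(model_file, "proq_model")) model_file
        else load_model(model_file)
  if (is.null(target_length)) target_length <- si$profile$length
  if (file.exists(out)) unlink(out)
  res <- lapply(model_paths, function(p) {
    model <- read_pdb(p)
    feats <- model_features(model, si$profile, si$ss_pred, si$exp_pred,
                            config = config)
    local_s <- predict_local(qa, feats)
    global <- predict_global(local_s, target_length)
    s_target <- rep(NA_real_, target_length)
    s_target[model$target_pos] <- local_s
    write_qa_record(out, model$model_id, global, s_target, config = config)
    data.frame(model_id = model$model_id, global = global,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, res))
}

#' Train a regressor from a feature/truth table
#'
#' @param features_tsv TSV with columns target, model, residue, true_s and
#'   one column per feature component.
#' @param out output JSON model file.
#' @param config a \code{proq_config} (grids and seed are taken from it).
#' @return invisibly, the trained \code{proq_model}.
#' @export
run_train <- function(features_tsv, out, config = proq_config()) {
  df <- utils::read.delim(features_tsv, check.names = FALSE)
  meta <- c("target", "model", "residue", "true_s")
  stopifnot(all(meta %in% names(df)))
  fit <- proq_train(as.matrix(df[, setdiff(names(df), meta)]),
                    df$true_s, df$target,
                    C_grid = config$C_grid, eps_grid = config$eps_grid,
                    seed = config$seed)
  save_model(fit, out)
  invisible(fit)
}

#' Evaluate predictions against truths
#'
#' @param pred_tsv TSV with columns target, model, predicted (global) or
#'   target, model, residue, predicted (local).
#' @param truth_tsv TSV keyed the same way with true_quality / true_s (and
#'   true_d for local ROC statistics).
#' @param out optional JSON report path.
#' @param level "global" or "local".
#' @return the report list.
#' @export
run_eval <- function(pred_tsv, truth_tsv, out = NULL, level = "global") {
  pred <- utils::read.delim(pred_tsv)
  truth <- utils::read.delim(truth_tsv)
  key <- intersect(c("target", "model", "residue"), names(pred))
  df <- merge(pred, truth, by = key)
  rep <- if (level == "global") evaluate_global(df) else evaluate_local(df)
  if (!is.null(out))
    jsonlite::write_json(rep, out, auto_unbox = TRUE, digits = NA)
  rep
}

#' Consensus-score a directory (or list) of models
#'
#' @param model_paths PDB files of one target's models.
#' @param out optional QA output file.
#' @param k combination weight; used when \code{single_scores} are given.
#' @param single_scores optional named vector of single-model global scores
#'   (names = model ids) to combine with the consensus score.
#' @param config a \code{proq_config}.
#' @return data.frame with model_id, pcons and (when combined) combined.
#' @export
run_consensus <- function(model_paths, out = NULL, k = 0.8,
                          single_scores = NULL, config = proq_config()) {
  if (length(model_paths) < 2) stop("consensus needs at least 2 models")
  ensemble <- lapply(model_paths, read_pdb)
  res <- pcons_ensemble(ensemble, d0 = config$d0)
  if (!is.null(single_scores)) {
    sm <- single_scores[res$model_id]
    if (anyNA(sm)) stop("single_scores missing for some models")
    res$combined <- combine_scores(sm, res$pcons, k = k)
  }
  if (!is.null(out)) {
    if (file.exists(out)) unlink(out)
    for (i in seq_len(nrow(res))) {
      g <- if (!is.null(res$combined)) res$combined[i] else res$pcons[i]
      mod <- ensemble[[i]]
      s_target <- rep(NA_real_, mod$target_length)
      s_target[mod$target_pos] <- pcons_score(ensemble, i, d0 = config$d0)$local
      write_qa_record(out, res$model_id[i], g, s_target, config = config)
    }
  }
  res
}

#' Export a feature matrix with metadata columns as TSV
#'
#' @param df data.frame as written by the \code{features} CLI subcommand.
#' @param path output TSV.
#' @export
write_feature_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
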