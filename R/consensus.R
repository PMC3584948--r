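# Structural consensus scoring over a model ensemble and the linear
# combination of single-model and consensus scores.

#' Consensus quality of one model within an ensemble
#'
#' The local consensus score of residue r is the mean, over all other models
#' of the same target, of the per-residue S-score similarity obtained from
#' the S-score-optimal superposition of this model onto the other; the
#' global score is the sum of local scores divided by the target length.
#' Models that agree structurally with the rest of the ensemble score high.
#'
#' @param ensemble list of \code{protein_model}s for one target (>= 2).
#' @param index which model to score.
#' @param d0 S-score distance threshold, Angstrom.
#' @return list with \code{local} (per modeled residue of the scored model)
#'   and \code{global} in [0,1].
#' @export
pcons_score <- function(ensemble, index, d0 = 3) {
  if (length(ensemble) < 2)
    stop("consensus undefined for an ensemble of fewer than 2 models")
  model <- ensemble[[index]]
  others <- ensemble[-index]
  acc <- matrix(0, model$target_length, length(others))
  for (k in seq_along(others)) {
    res <- optimal_s_superposition(model, others[[k]], d0 = d0)
    acc[, k] <- res$local$s[seq_len(model$target_length)]
  }
  local_target <- rowMeans(acc)
  list(local = local_target[model$target_pos],
       global = sum(local_target) / model$target_length)
}

#' Consensus scores for every model of an ensemble
#'
#' @inheritParams pcons_score
#' @return data.frame with one row per model: model_id, global consensus
#'   score.
#' @export
pcons_ensemble <- function(ensemble, d0 = 3) {
  glob <- vapply(seq_along(ensemble),
                 function(i) pcons_score(ensemble, i, d0 = d0)$global,
                 numeric(1))
  data.frame(model_id = vapply(ensemble, `[[`, character(1), "model_id"),
             pcons = glob, stringsAsFactors = FALSE)
}

#' Linear combination of single-model and consensus scores
#'
#' S_combined = (1 - k) * S_single + k * S_consensus. The default weight
#' k = 0.8 gives the consensus score four times the weight of the
#' single-model score; k is exposed so it can be re-optimized on any
#' labeled ensemble set.
#'
#' @param s_single single-model score(s) in [0,1].
#' @param s_consensus consensus score(s) in [0,1].
#' @param k consensus weight in [0,1].
#' @return combined score(s) in [0,1].
#' @export
combine_scores <- function(s_single, s_consensus, k = 0.8) {
  stopifnot(k >= 0, k <= 1)
  if (any(s_single < 0 | s_single > 1, na.rm = TRUE) ||
      any(s_consensus < 0 | s_consensus > 1, na.rm = TRUE))
    stop("scores must lie in [0,1]")
  (1 - k) * s_single + k * s_consensus
}

#' Re-optimize the combination weight on a labeled ensemble set
#'
#' Scans k over a grid and returns the k maximizing the summed true quality
#' (e.g. GDT_TS) of the first-ranked model per target.
#'
#' @param scores data.frame with columns target, s_single, s_consensus and
#'   true_quality (one row per model).
#' @param k_grid candidate weights.
#' @return list with \code{k} and the selection curve (\code{gdt1} per k).
#' @export
optimize_k <- function(scores, k_grid = seq(0, 1, by = 0.05)) {
  stopifnot(all(c("target", "s_single", "s_consensus", "true_quality")
                %in% names(scores)))
  curve <- vapply(k_grid, function(k) {
    comb <- combine_scores(scores$s_single, scores$s_consensus, k)
    sum(vapply(split(data.frame(comb, q = scores$true_quality), scores$target),
               function(df) df$q[which.max(df$comb)], numeric(1)))
  }, numeric(1))
  list(k = k_grid[which.max(curve)],
       curve = data.frame(k = k_grid, gdt1 = curve))
}
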