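# Benchmark statistics for quality-assessment methods: correlation at
# several levels, the Fisher R-to-z comparison of correlations, model
# selection measures (GDT1, per-target Z-scores, bootstrap support) and
# residue-level discrimination (ROC on correct/incorrect residues,
# top-fraction deviation curves).

#' Pearson correlation
#'
#' @param x,y numeric vectors.
#' @return Pearson's R.
#' @export
pearson <- function(x, y) stats::cor(x, y, method = "pearson")

#' Compare two correlation coefficients via Fisher's R-to-z transform
#'
#' z = 0.5 * (ln(1+R) - ln(1-R)) is approximately normal with variance
#' 1/(n-3); the two-sided P-value of |z1 - z2| estimates whether the
#' correlations differ.
#'
#' @param r1,r2 correlation coefficients, |R| < 1.
#' @param n1,n2 number of observations behind each coefficient (> 3).
#' @return list with \code{z1}, \code{z2}, \code{z_diff} (standardized
#'   difference) and two-sided \code{p_value}.
#' @export
fisher_z_test <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("correlations must satisfy |R| < 1")
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 observations")
  z1 <- 0.5 * (log(1 + r1) - log(1 - r1))
  z2 <- 0.5 * (log(1 + r2) - log(1 - r2))
  zd <- (z1 - z2) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z1 = z1, z2 = z2, z_diff = zd,
       p_value = 2 * stats::pnorm(-abs(zd)))
}

#' Sum of true quality of the first-ranked model per target (GDT1)
#'
#' @param df data.frame with columns \code{target}, \code{predicted} (the
#'   method's global score) and \code{true_quality} (e.g. GDT_TS).
#' @return sum over targets of the true quality of the model each target's
#'   highest predicted score selects.
#' @export
gdt1 <- function(df) {
  stopifnot(all(c("target", "predicted", "true_quality") %in% names(df)))
  sum(vapply(split(df, df$target),
             function(d) d$true_quality[which.max(d$predicted)], numeric(1)))
}

#' Per-target selection Z-score
#'
#' Standardizes the quality of the selected model against the quality
#' distribution of all models for the target: (q_selected - mean) / sd.
#' A random pick has expected Z of zero. Targets where all models have
#' identical quality are reported as Z = 0 with \code{degenerate = TRUE}.
#'
#' @param selected_quality quality of the selected model.
#' @param target_qualities qualities of all models of the target.
#' @return list with \code{z} and \code{degenerate}.
#' @export
selection_zscore <- function(selected_quality, target_qualities) {
  sdev <- stats::sd(target_qualities)
  if (!is.finite(sdev) || sdev == 0)
    return(list(z = 0, degenerate = TRUE))
  list(z = (selected_quality - mean(target_qualities)) / sdev,
       degenerate = FALSE)
}

#' ROC for recognizing correct and incorrect residues
#'
#' Residues deviating less than \code{correct_cut} are positives, residues
#' deviating more than \code{incorrect_cut} negatives; residues in between
#' are excluded. The curve sweeps the predicted score as threshold
#' (higher score = predicted correct).
#'
#' @param predicted_s predicted per-residue scores.
#' @param true_d true per-residue distance deviations (Angstrom).
#' @param correct_cut,incorrect_cut class cutoffs (Angstrom).
#' @return list with \code{points} (data.frame fpr, tpr), \code{auc} and the
#'   class counts \code{n_pos}, \code{n_neg}.
#' @export
roc_correct_incorrect <- function(predicted_s, true_d,
                                  correct_cut = 3, incorrect_cut = 5) {
  keep <- true_d < correct_cut | true_d > incorrect_cut
  sc <- predicted_s[keep]
  pos <- true_d[keep] < correct_cut
  if (!any(pos) || all(pos)) stop("need both correct and incorrect residues")
  thr <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(sc[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(sc[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
       n_pos = sum(pos), n_neg = sum(!pos))
}

#' Mean true deviation of the top-ranked residue fractions
#'
#' Residues are ranked by predicted score (best first); for each fraction f
#' the mean true distance deviation of the top f of residues is reported.
#' For a perfect predictor the curve is the running mean of the sorted
#' deviations and is non-decreasing in f.
#'
#' @param predicted_s predicted per-residue scores.
#' @param true_d true distance deviations.
#' @param fractions fractions in (0,1].
#' @return data.frame with columns fraction, mean_d.
#' @export
top_fraction_deviation <- function(predicted_s, true_d,
                                   fractions = seq(0.05, 1, by = 0.05)) {
  ord <- order(predicted_s, decreasing = TRUE)
  d <- true_d[ord]
  n <- length(d)
  data.frame(fraction = fractions,
             mean_d = vapply(fractions, function(f)
               mean(d[seq_len(max(1, round(f * n)))]), numeric(1)))
}

#' Bootstrap support that one method selects better models than another
#'
#' Resamples targets with replacement; the support is the fraction of
#' resamples in which method A's summed first-ranked quality exceeds
#' method B's (ties count 0.5).
#'
#' @param gdt_a,gdt_b per-target first-ranked qualities of the two methods
#'   (aligned by target).
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return support in [0,1].
#' @export
bootstrap_support <- function(gdt_a, gdt_b, n_boot = 1000, seed = 1) {
  stopifnot(length(gdt_a) == length(gdt_b))
  n <- length(gdt_a)
  set.seed(seed)
  wins <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    sa <- sum(gdt_a[idx]); sb <- sum(gdt_b[idx])
    wins <- wins + (sa > sb) + 0.5 * (sa == sb)
  }
  wins / n_boot
}

#' Local-quality evaluation report
#'
#' Pooled Pearson correlation over all residues, mean per-target correlation
#' and mean per-model correlation between predicted and true local scores.
#' Groups with zero variance in either vector are excluded from the means
#' and counted.
#'
#' @param df data.frame with columns target, model, predicted, true_s.
#' @return list with \code{r}, \code{r_target}, \code{r_model}, \code{n} and
#'   the number of groups excluded.
#' @export
evaluate_local <- function(df) {
  stopifnot(all(c("target", "model", "predicted", "true_s") %in% names(df)))
  grp_r <- function(key) {
    rs <- vapply(split(df, key), function(d) {
      if (stats::sd(d$predicted) == 0 || stats::sd(d$true_s) == 0)
        return(NA_real_)
      pearson(d$predicted, d$true_s)
    }, numeric(1))
    list(mean = mean(rs, na.rm = TRUE), excluded = sum(is.na(rs)))
  }
  rt <- grp_r(df$target)
  rm_ <- grp_r(paste(df$target, df$model))
  list(r = pearson(df$predicted, df$true_s),
       r_target = rt$mean, r_model = rm_$mean,
       n = nrow(df), excluded_targets = rt$excluded,
       excluded_models = rm_$excluded)
}

#' Global-quality evaluation report
#'
#' Pooled and mean per-target correlation between predicted and true global
#' quality, GDT1 and the summed selection Z-score.
#'
#' @param df data.frame with columns target, model, predicted, true_quality.
#' @return list with \code{r}, \code{r_target}, \code{gdt1}, \code{sum_z}
#'   and \code{n_degenerate} (targets skipped in the Z sum for zero quality
#'   variance).
#' @export
evaluate_global <- function(df) {
  stopifnot(all(c("target", "model", "predicted", "true_quality")
                %in% names(df)))
  per_t <- split(df, df$target)
  rs <- vapply(per_t, function(d) {
    if (stats::sd(d$predicted) == 0 || stats::sd(d$true_quality) == 0)
      return(NA_real_)
    pearson(d$predicted, d$true_quality)
  }, numeric(1))
  zs <- lapply(per_t, function(d)
    selection_zscore(d$true_quality[which.max(d$predicted)], d$true_quality))
  degen <- vapply(zs, `[[`, logical(1), "degenerate")
  list(r = pearson(df$predicted, df$true_quality),
       r_target = mean(rs, na.rm = TRUE),
       gdt1 = gdt1(df),
       sum_z = sum(vapply(zs[!degen], `[[`, numeric(1), "z")),
       n_degenerate = sum(degen))
}
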