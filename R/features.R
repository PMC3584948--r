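# Per-residue feature extraction. The environment of each residue is
# described over sliding sequence windows; features involving spatial
# contacts also count partners outside the window that touch window
# residues. Contact and exposure histograms are normalized within the
# window; residue-specific blocks can be profile-weighted, spreading each
# residue's contribution over amino-acid types according to its sequence
# profile. Two whole-model agreement features are appended to every
# residue's vector.

.UT13 <- which(upper.tri(matrix(0, 13, 13), diag = TRUE))
.UT6  <- which(upper.tri(matrix(0, 6, 6), diag = TRUE))

.pssm_groups <- function() assign_residue_group(PSSM_AA_ORDER)

#' Names of the feature-vector components, in layout order
#'
#' @param window base window length for contact/exposure features.
#' @return character vector naming all components.
#' @export
feature_names <- function(window = 21) {
  idx13 <- arrayInd(.UT13, c(13, 13))
  idx6 <- arrayInd(.UT6, c(6, 6))
  c(sprintf("atom_%d_%d", idx13[, 1], idx13[, 2]),
    sprintf("res_%d_%d", idx6[, 1], idx6[, 2]),
    sprintf("expo_g%d_b%d", rep(1:6, 4), rep(1:4, each = 6)),
    c("ss_prob_H", "ss_prob_E", "ss_prob_C"),
    "ss_agree_w21",
    sprintf("ss5_%d_%s", rep(1:5, each = 3), rep(c("H", "E", "C"), 5)),
    "surf_agree_w21", "surf_area_w13", "ipp_w3",
    "global_ss_agree", "global_surf_agree")
}

.window_idx <- function(center, half, n) max(1, center - half):min(n, center + half)

# atom pairs in contact: data.frame(i, j, ci, cj) with i/j residue indices,
# i < j in residue order, |i - j| >= min_sep (adjacent-in-sequence excluded)
.atom_contact_pairs <- function(model, cutoff = 4, min_sep = 2) {
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  sep <- abs(outer(at$res_i, at$res_i, "-"))
  hit <- which(upper.tri(d2) & d2 <= cutoff^2 & sep >= min_sep, arr.ind = TRUE)
  data.frame(i = at$res_i[hit[, 1]], j = at$res_i[hit[, 2]],
             ci = at$atom_class[hit[, 1]], cj = at$atom_class[hit[, 2]])
}

# residue pairs in contact: CA or side-chain atoms within cutoff, |i-j| > sep-1
.residue_contact_pairs <- function(model, cutoff = 6, min_sep = 6) {
  at <- model$atoms[model$atoms$elety == "CA" | model$atoms$is_sidechain, ]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  sep <- abs(outer(at$res_i, at$res_i, "-"))
  hit <- which(upper.tri(d2) & d2 <= cutoff^2 & sep >= min_sep, arr.ind = TRUE)
  if (!nrow(hit)) return(data.frame(i = integer(), j = integer()))
  unique(data.frame(i = pmin(at$res_i[hit[, 1]], at$res_i[hit[, 2]]),
                    j = pmax(at$res_i[hit[, 1]], at$res_i[hit[, 2]])))
}

# per-residue 6-group mass vectors (n x 6): one-hot on the model sequence,
# or the profile frequencies aggregated by group when a profile is given
.group_mass <- function(model, profile = NULL) {
  n <- n_residues(model)
  gm <- matrix(0, n, 6)
  if (is.null(profile)) {
    g <- assign_residue_group(model$aa)
    gm[cbind(seq_len(n), g)] <- 1
  } else {
    pg <- .pssm_groups()
    for (k in 1:6) {
      cols <- which(pg == k)
      gm[, k] <- rowSums(profile$freqs[model$target_pos, cols, drop = FALSE])
    }
  }
  gm
}

#' Atom-atom contact distribution around a residue
#'
#' Counts contacts between the 13 atom classes (atoms within the contact
#' cutoff, sequence-adjacent pairs excluded) where at least one atom belongs
#' to a residue of the window centered on \code{center}; the 13 x 13
#' upper-triangle histogram is normalized by the total count (all-zero when
#' the window has no contacts).
#'
#' @param model a \code{protein_model}.
#' @param center residue index (1-based).
#' @param window window length (odd).
#' @param cutoff contact cutoff, Angstrom.
#' @param pairs optional precomputed pair table (internal use).
#' @return numeric vector of length 91.
#' @export
atom_contact_features <- function(model, center, window = 21, cutoff = 4,
                                  pairs = NULL) {
  if (is.null(pairs)) pairs <- .atom_contact_pairs(model, cutoff = cutoff)
  w <- .window_idx(center, (window - 1) %/% 2, n_residues(model))
  sel <- pairs$i %in% w | pairs$j %in% w
  M <- matrix(0, 13, 13)
  if (any(sel)) {
    a <- pmin(pairs$ci[sel], pairs$cj[sel])
    b <- pmax(pairs$ci[sel], pairs$cj[sel])
    for (k in seq_along(a)) M[a[k], b[k]] <- M[a[k], b[k]] + 1
    M <- M / sum(M)
  }
  M[.UT13]
}

#' Residue-residue contact distribution around a residue
#'
#' Residues are in contact when any CA or side-chain atom pair is within the
#' cutoff and the residues are more than \code{min_sep - 1} apart in
#' sequence. Contacts touching the window are accumulated into a 6 x 6
#' group histogram; with a sequence profile each endpoint contributes
#' fractionally to the groups according to its per-position amino-acid
#' frequencies.
#'
#' @inheritParams atom_contact_features
#' @param profile optional \code{sequence_profile} for profile weighting.
#' @param cutoff contact cutoff (Angstrom).
#' @param min_sep minimum sequence separation (contacts require
#'   |i - j| >= min_sep).
#' @param gmass optional precomputed per-residue group-mass matrix
#'   (internal use).
#' @return numeric vector of length 21.
#' @export
residue_contact_features <- function(model, center, profile = NULL,
                                     window = 21, cutoff = 6, min_sep = 6,
                                     pairs = NULL, gmass = NULL) {
  if (is.null(pairs))
    pairs <- .residue_contact_pairs(model, cutoff = cutoff, min_sep = min_sep)
  if (is.null(gmass)) gmass <- .group_mass(model, profile)
  w <- .window_idx(center, (window - 1) %/% 2, n_residues(model))
  sel <- which(pairs$i %in% w | pairs$j %in% w)
  M <- matrix(0, 6, 6)
  for (k in sel) {
    S <- outer(gmass[pairs$i[k], ], gmass[pairs$j[k], ])
    S <- S + t(S)
    diag(S) <- diag(S) / 2
    M <- M + S
  }
  if (length(sel)) M <- M / length(sel)
  # symmetric mass already folded; read the upper triangle
  M[.UT6]
}

#' Exposure-pattern features around a residue
#'
#' Each window residue adds (profile-weighted) mass at (residue group,
#' exposure bin), bins <25%, 25-50%, 50-75%, >=75% (left-closed boundaries);
#' the 6 x 4 block is normalized by the number of residues in the window.
#'
#' @inheritParams residue_contact_features
#' @param sasa per-residue relative exposures in [0,1]
#'   (\code{\link{compute_sasa}}).
#' @return numeric vector of length 24 (groups fastest).
#' @export
exposure_features <- function(model, center, sasa, profile = NULL,
                              window = 21, gmass = NULL) {
  if (is.null(gmass)) gmass <- .group_mass(model, profile)
  w <- .window_idx(center, (window - 1) %/% 2, n_residues(model))
  M <- matrix(0, 6, 4)
  bins <- findInterval(sasa[w], c(0.25, 0.5, 0.75)) + 1L
  for (k in seq_along(w)) M[, bins[k]] <- M[, bins[k]] + gmass[w[k], ]
  M <- M / length(w)
  as.vector(M)
}

#' Secondary-structure agreement features
#'
#' Three blocks: the predicted class probabilities at the central residue;
#' the fraction of a (truncated) 21-residue window where the predicted class
#' matches the assigned one; and the assigned classes one-hot encoded over a
#' 5-residue window (positions beyond the termini all-zero).
#'
#' @param assigned character vector of assigned classes ("H"/"E"/"C") per
#'   model residue.
#' @param ss_pred a \code{ss_prediction} over target positions.
#' @param model a \code{protein_model} (for the target mapping).
#' @param center residue index.
#' @param window agreement window length.
#' @param window5 one-hot window length.
#' @return list with \code{central} (3 probs H/E/C), \code{agree} (fraction)
#'   and \code{onehot} (length 3 * window5).
#' @export
ss_agreement_features <- function(assigned, ss_pred, model, center,
                                  window = 21, window5 = 5) {
  n <- n_residues(model)
  tp <- model$target_pos
  w <- .window_idx(center, (window - 1) %/% 2, n)
  agree <- mean(ss_pred$class[tp[w]] == assigned[w])
  half5 <- (window5 - 1) %/% 2
  onehot <- matrix(0, 3, window5, dimnames = list(c("H", "E", "C"), NULL))
  for (o in -half5:half5) {
    r <- center + o
    if (r >= 1 && r <= n) onehot[assigned[r], o + half5 + 1] <- 1
  }
  list(central = ss_pred$prob[tp[center], ], agree = agree,
       onehot = as.vector(onehot))
}

#' Surface-area agreement features
#'
#' Residues exposing less than 25% of the side chain are "buried"; the
#' agreement fraction compares that class with the predicted burial over a
#' (truncated) 21-residue window, and the mean relative exposure is taken
#' over a 13-residue window.
#'
#' @param sasa per-residue relative exposures.
#' @param exp_pred an \code{exposure_prediction} over target positions.
#' @param model a \code{protein_model}.
#' @param center residue index.
#' @param window agreement window length.
#' @param window13 area window length.
#' @param buried_cut relative-exposure threshold for the buried class.
#' @return list with \code{agree} and \code{area}.
#' @export
surface_agreement_features <- function(sasa, exp_pred, model, center,
                                       window = 21, window13 = 13,
                                       buried_cut = 0.25) {
  n <- n_residues(model)
  tp <- model$target_pos
  actual <- ifelse(sasa < buried_cut, "b", "e")
  w <- .window_idx(center, (window - 1) %/% 2, n)
  agree <- mean(exp_pred$class[tp[w]] == actual[w])
  w13 <- .window_idx(center, (window13 - 1) %/% 2, n)
  list(agree = agree, area = mean(sasa[w13]))
}

#' Mean information-per-position over a short window
#'
#' @param profile a \code{sequence_profile}.
#' @param model a \code{protein_model}.
#' @param center residue index.
#' @param window window length (default 3).
#' @return mean IPP (bits) over the truncated window.
#' @export
ipp_feature <- function(profile, model, center, window = 3) {
  w <- .window_idx(center, (window - 1) %/% 2, n_residues(model))
  mean(profile$ipp[model$target_pos[w]])
}

#' Whole-model agreement features
#'
#' The same secondary-structure and burial agreement fractions as the
#' windowed features, averaged over all modeled residues. These are global
#' descriptors appended to every residue's feature vector.
#'
#' @param model a \code{protein_model}.
#' @param sasa per-residue relative exposures.
#' @param assigned assigned secondary-structure classes.
#' @param ss_pred a \code{ss_prediction}.
#' @param exp_pred an \code{exposure_prediction}.
#' @param buried_cut burial threshold.
#' @return named numeric vector (ss_agree, surf_agree).
#' @export
global_features <- function(model, sasa, assigned, ss_pred, exp_pred,
                            buried_cut = 0.25) {
  tp <- model$target_pos
  actual <- ifelse(sasa < buried_cut, "b", "e")
  c(ss_agree = mean(ss_pred$class[tp] == assigned),
    surf_agree = mean(exp_pred$class[tp] == actual))
}

#' Feature vector of one residue
#'
#' Concatenates, in fixed order: atom-contact block (91), residue-contact
#' block (21, profile-weighted when a profile is given), exposure block (24,
#' profile-weighted), central secondary-structure probabilities (3), the
#' 21-window secondary-structure agreement (1), assigned classes over a
#' 5-window (15), the 21-window burial agreement (1), 13-window mean surface
#' area (1), 3-window mean information per position (1) and the two global
#' agreement features (2): 160 components.
#'
#' @param model a \code{protein_model}.
#' @param center residue index.
#' @param profile \code{sequence_profile}.
#' @param ss_pred \code{ss_prediction}.
#' @param exp_pred \code{exposure_prediction}.
#' @param sasa optional precomputed relative exposures.
#' @param assigned optional precomputed secondary-structure classes.
#' @param config a \code{\link{proq_config}} list.
#' @return named numeric vector of length 160.
#' @export
build_feature_vector <- function(model, center, profile, ss_pred, exp_pred,
                                 sasa = NULL, assigned = NULL,
                                 config = proq_config()) {
  if (is.null(sasa))
    sasa <- compute_sasa(model, probe = config$probe,
                         n_points = config$sasa_points)
  if (is.null(assigned)) assigned <- assign_secondary_structure(model)
  model_features(model, profile, ss_pred, exp_pred, sasa = sasa,
                 assigned = assigned, config = config)[center, ]
}

#' Feature matrix of a whole model
#'
#' Computes \code{\link{build_feature_vector}} for every residue, sharing
#' the contact lists, SASA and secondary-structure assignment across
#' residues.
#'
#' @inheritParams build_feature_vector
#' @return numeric matrix n_residues x 160 with \code{\link{feature_names}}
#'   as column names.
#' @export
model_features <- function(model, profile, ss_pred, exp_pred,
                           sasa = NULL, assigned = NULL,
                           config = proq_config()) {
  n <- n_residues(model)
  if (is.null(sasa))
    sasa <- compute_sasa(model, probe = config$probe,
                         n_points = config$sasa_points)
  if (is.null(assigned)) assigned <- assign_secondary_structure(model)
  apairs <- .atom_contact_pairs(model, cutoff = config$atom_cutoff,
                                min_sep = config$atom_min_sep)
  rpairs <- .residue_contact_pairs(model, cutoff = config$res_cutoff,
                                   min_sep = config$res_min_sep)
  gmass <- .group_mass(model, profile)
  glob <- global_features(model, sasa, assigned, ss_pred, exp_pred,
                          buried_cut = config$buried_cut)
  w <- config$window
  out <- matrix(0, n, length(feature_names(w)),
                dimnames = list(NULL, feature_names(w)))
  for (r in seq_len(n)) {
    ssf <- ss_agreement_features(assigned, ss_pred, model, r,
                                 window = config$window_ss,
                                 window5 = config$window_ss5)
    sf <- surface_agreement_features(sasa, exp_pred, model, r,
                                     window = config$window_surf,
                                     window13 = config$window_area,
                                     buried_cut = config$buried_cut)
    out[r, ] <- c(
      atom_contact_features(model, r, window = w, pairs = apairs),
      residue_contact_features(model, r, profile = profile, window = w,
                               pairs = rpairs, gmass = gmass),
      exposure_features(model, r, sasa, profile = profile, window = w,
                        gmass = gmass),
      ssf$central, ssf$agree, ssf$onehot,
      sf$agree, sf$area,
      ipp_feature(profile, model, r, window = config$window_ipp),
      glob)
  }
  out
}
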