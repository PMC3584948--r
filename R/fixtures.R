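# Synthetic fixtures with known ground truth: ideal-geometry native
# structures, perturbed model ensembles emulating the quality spread of a
# prediction-target model set, and matching sequence-derived prediction
# files in the dialects the readers understand. Every generator takes an
# explicit seed and is deterministic given it.

# place atom D bonded to C: bond length r, angle theta(B,C,D) and dihedral
# chi(A,B,C,D), angles in degrees (natural extension of reference frames)
.nerf <- function(A, B, C, r, theta, chi) {
  th <- theta * pi / 180; ch <- -chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  C + d[1] * bc + d[2] * m2 + d[3] * n
}

.place_cb <- function(N, CA, C) {
  u <- N - CA; u <- u / sqrt(sum(u^2))
  v <- C - CA; v <- v / sqrt(sum(v^2))
  bis <- u + v; bis <- bis / sqrt(sum(bis^2))
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  cosg <- sum(bis * u)
  a <- cos(110.4 * pi / 180) / cosg
  b <- sqrt(max(0, 1 - a^2))
  CA + 1.53 * (a * bis + b * nrm)
}

.fold_dihedrals <- function(n, fold) {
  switch(fold,
    helix = list(phi = rep(-57, n), psi = rep(-47, n)),
    sheet = list(phi = rep(-135, n), psi = rep(135, n)),
    coil = list(phi = -100 + 70 * sin(seq_len(n) * 2.39),
                psi = 60 + 100 * cos(seq_len(n) * 1.73)),
    two_domain = {
      half <- n %/% 2
      phi <- rep(-57, n); psi <- rep(-47, n)
      link <- (half - 1):(half + 2)
      link <- link[link >= 1 & link <= n]
      phi[link] <- -135; psi[link] <- 135
      list(phi = phi, psi = psi)
    },
    stop("unknown fold: ", fold))
}

#' Generate an ideal-geometry native structure
#'
#' Builds a backbone (N, CA, C, O) from per-residue phi/psi dihedrals with
#' ideal bond lengths and angles, plus a CB placeholder side chain (absent
#' for Gly). Folds: a straight alpha helix, an extended strand, an irregular
#' coil, or two helical domains joined by an extended linker.
#'
#' @param n_residues chain length.
#' @param fold one of "helix", "sheet", "coil", "two_domain".
#' @param sequence optional one-letter sequence (random otherwise).
#' @param seed RNG seed for the random sequence.
#' @param model_id identifier.
#' @return a \code{protein_model}.
#' @export
make_native <- function(n_residues, fold = "helix", sequence = NULL,
                        seed = 1, model_id = paste0("native_", fold)) {
  stopifnot(n_residues >= 3)
  if (is.null(sequence)) {
    set.seed(seed)
    sequence <- sample(names(AA1), n_residues, replace = TRUE)
  }
  stopifnot(length(sequence) == n_residues)
  di <- .fold_dihedrals(n_residues, fold)
  N <- matrix(0, n_residues, 3); CA <- N; C <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, di$psi[i])
    CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], 1.458, 121.7, 180)
    C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], 1.525, 111.2,
                        di$phi[i + 1])
  }
  rows <- list()
  for (i in seq_len(n_residues)) {
    O <- if (i < n_residues)
      .nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, di$psi[i] + 180)
    else .nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, 0)
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O)
    ety <- c("N", "CA", "C", "O")
    if (sequence[i] != "G") {
      xyz <- rbind(xyz, .place_cb(N[i, ], CA[i, ], C[i, ]))
      ety <- c(ety, "CB")
    }
    rows[[i]] <- data.frame(res_i = i, elety = ety,
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  protein_model(do.call(rbind, rows), sequence, model_id = model_id)
}

#' Generate a perturbed model ensemble with known true quality
#'
#' Each model displaces every residue of the native by an independent
#' Gaussian 3-vector of scale sigma (applied to all atoms of the residue) and
#' then applies a random rigid motion; true per-residue deviations, S-scores
#' and GDT_TS are computed against the native with the package's own
#' superposition machinery.
#'
#' @param native a \code{protein_model}.
#' @param sigmas displacement scale (Angstrom) per model; 0 reproduces the
#'   native.
#' @param seed RNG seed.
#' @param d0 S-score threshold.
#' @return list with \code{models} (list of \code{protein_model}),
#'   \code{truth_local} (model_id, target_pos, d, s) and \code{truth_global}
#'   (model_id, sigma, s_global, gdt_ts).
#' @export
make_ensemble <- function(native, sigmas, seed = 1, d0 = 3) {
  set.seed(seed)
  n <- n_residues(native)
  models <- vector("list", length(sigmas))
  tl_rows <- list(); tg_rows <- list()
  for (m in seq_along(sigmas)) {
    at <- native$atoms
    disp <- matrix(stats::rnorm(n * 3, sd = sigmas[m]), n, 3)
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] + disp[at$res_i, ]
    # random rigid motion; removed again by any superposition
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    angle <- stats::runif(1, 0, 2 * pi)
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
    xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
    xyz <- sweep(xyz, 2, stats::rnorm(3, sd = 10), "+")
    at[, c("x", "y", "z")] <- xyz
    id <- sprintf("%s_m%02d", native$model_id, m)
    mod <- protein_model(at, native$aa, model_id = id,
                         target_pos = native$target_pos,
                         target_length = native$target_length)
    models[[m]] <- mod
    sim <- optimal_s_superposition(mod, native, d0 = d0)
    tl_rows[[m]] <- data.frame(model_id = id,
                               target_pos = sim$local$target_pos,
                               d = sim$local$d, s = sim$local$s,
                               stringsAsFactors = FALSE)
    tg_rows[[m]] <- data.frame(model_id = id, sigma = sigmas[m],
                               s_global = sim$sum_s / native$target_length,
                               gdt_ts = gdt_ts(mod, native),
                               stringsAsFactors = FALSE)
  }
  list(models = models,
       truth_local = do.call(rbind, tl_rows),
       truth_global = do.call(rbind, tg_rows))
}

#' Write a sequence profile in the PSI-BLAST ASCII PSSM dialect
#'
#' @param query one-letter query sequence.
#' @param freqs n x 20 frequency matrix (PSI-BLAST amino-acid column order).
#' @param ipp per-position information (bits).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pssm <- function(query, freqs, ipp, path) {
  n <- length(query)
  stopifnot(nrow(freqs) == n, length(ipp) == n)
  bg <- 0.05
  logodds <- round(2 * log2(pmax(freqs, 1e-4) / bg))
  pct <- round(freqs * 100)
  hdr <- paste0("           ",
                paste(sprintf("%3s", PSSM_AA_ORDER), collapse = ""),
                " ",
                paste(sprintf("%4s", PSSM_AA_ORDER), collapse = ""))
  lines <- c("", "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
             hdr)
  for (i in seq_len(n)) {
    lines <- c(lines, paste0(
      sprintf("%5d %s  ", i, query[i]),
      paste(sprintf("%3d", logodds[i, ]), collapse = " "), "  ",
      paste(sprintf("%3d", pct[i, ]), collapse = " "),
      sprintf("  %.2f %.2f", ipp[i], 1)))
  }
  writeLines(c(lines, "", ""), path)
  invisible(path)
}

#' Write a PSIPRED-style .ss2 prediction file
#'
#' @param aa one-letter sequence.
#' @param prob n x 3 probability matrix, columns H, E, C.
#' @param path output file.
#' @export
write_ss2 <- function(aa, prob, path) {
  cls <- c("H", "E", "C")[max.col(prob, ties.method = "first")]
  lines <- c("# PSIPRED VFORMAT (synthetic)", "")
  for (i in seq_along(aa))
    lines <- c(lines, sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                              i, aa[i], cls[i],
                              prob[i, 3], prob[i, 1], prob[i, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a two-line burial/exposure prediction file
#'
#' @param aa one-letter sequence.
#' @param class character vector of "b"/"e".
#' @param path output file.
#' @export
write_exposure_prediction <- function(aa, class, path) {
  stopifnot(length(aa) == length(class), all(class %in% c("b", "e")))
  writeLines(c(paste(aa, collapse = ""), paste(class, collapse = "")), path)
  invisible(path)
}

#' Generate sequence-derived prediction inputs for a native structure
#'
#' Secondary-structure and burial predictions agree with the native's
#' assigned classes with probability \code{accuracy} (disagreements drawn
#' uniformly from the other classes); the sequence profile is the one-hot
#' native sequence blended with a uniform background. Optionally writes the
#' PSSM/.ss2/exposure files.
#'
#' @param native a \code{protein_model}.
#' @param accuracy probability a predicted class matches the assigned one.
#' @param profile_mix fraction of profile mass spread uniformly over the 20
#'   amino acids (multiples of 0.2 keep the written integer percentages
#'   exact).
#' @param seed RNG seed.
#' @param dir optional directory; when given, files
#'   \code{<model_id>.pssm/.ss2/.acc/.fasta} are written there.
#' @param sasa optional precomputed relative exposures of the native.
#' @return list with \code{profile}, \code{ss_pred}, \code{exp_pred} (typed
#'   objects as the readers return), the native's \code{assigned_ss} and
#'   \code{exposure_class}, and \code{paths} when \code{dir} was given.
#' @export
make_sequence_inputs <- function(native, accuracy = 0.85, profile_mix = 0.4,
                                 seed = 1, dir = NULL, sasa = NULL) {
  set.seed(seed)
  n <- n_residues(native)
  aa <- native$aa
  assigned <- assign_secondary_structure(native)
  if (is.null(sasa)) sasa <- compute_sasa(native)
  expo <- ifelse(sasa < 0.25, "b", "e")

  mis <- stats::runif(n) > accuracy
  ss_cls <- assigned
  ss_cls[mis] <- vapply(assigned[mis], function(cl)
    sample(setdiff(c("H", "E", "C"), cl), 1), character(1))
  prob <- matrix(0.09, n, 3, dimnames = list(NULL, c("H", "E", "C")))
  prob[cbind(seq_len(n), match(ss_cls, colnames(prob)))] <- 0.82

  mis_e <- stats::runif(n) > accuracy
  acc_cls <- expo
  acc_cls[mis_e] <- ifelse(expo[mis_e] == "b", "e", "b")

  freqs <- matrix(profile_mix / 20, n, 20,
                  dimnames = list(NULL, PSSM_AA_ORDER))
  freqs[cbind(seq_len(n), match(aa, PSSM_AA_ORDER))] <-
    freqs[cbind(seq_len(n), match(aa, PSSM_AA_ORDER))] + (1 - profile_mix)
  ipp <- rowSums(freqs * log2(freqs / 0.05))

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    base <- file.path(dir, native$model_id)
    paths <- list(pssm = paste0(base, ".pssm"), ss2 = paste0(base, ".ss2"),
                  acc = paste0(base, ".acc"), fasta = paste0(base, ".fasta"))
    write_pssm(aa, freqs, ipp, paths$pssm)
    write_ss2(aa, prob, paths$ss2)
    write_exposure_prediction(aa, acc_cls, paths$acc)
    bio3d::write.fasta(ids = native$model_id, seqs = aa, file = paths$fasta)
    profile <- read_pssm(paths$pssm)
    ss_pred <- read_ss2(paths$ss2)
    exp_pred <- read_exposure_prediction(paths$acc)
  } else {
    profile <- structure(list(length = n, query = aa, freqs = freqs,
                              pssm = round(2 * log2(pmax(freqs, 1e-4) / 0.05)),
                              ipp = ipp), class = "sequence_profile")
    ss_pred <- structure(list(length = n, aa = aa, prob = prob,
                              class = colnames(prob)[max.col(prob, ties.method = "first")]),
                         class = "ss_prediction")
    exp_pred <- structure(list(length = n, aa = aa, class = acc_cls),
                          class = "exposure_prediction")
  }
  list(profile = profile, ss_pred = ss_pred, exp_pred = exp_pred,
       assigned_ss = assigned, exposure_class = expo, sasa = sasa,
       paths = paths)
}

#' Generate a self-contained synthetic benchmark
#'
#' For each target: an ideal native (cycling through folds), an ensemble of
#' perturbed models spanning near-native to essentially random, and matching
#' sequence-input predictions. When \code{dir} is given, writes
#' \code{natives/}, \code{models/}, \code{seqinputs/} and \code{truth.tsv}.
#'
#' @param n_targets number of targets.
#' @param n_models models per target.
#' @param n_residues residues per target.
#' @param sigma_max largest displacement scale (Angstrom); per-model scales
#'   are spaced from 0 to \code{sigma_max}.
#' @param accuracy sequence-prediction accuracy (see
#'   \code{\link{make_sequence_inputs}}).
#' @param seed RNG seed.
#' @param dir optional output directory.
#' @return list of per-target entries (native, models, seqinputs, truths).
#' @export
make_benchmark <- function(n_targets = 20, n_models = 10, n_residues = 60,
                           sigma_max = 8, accuracy = 0.85, seed = 1,
                           dir = NULL) {
  folds <- c("helix", "two_domain", "coil", "sheet")
  sigmas <- seq(0, sigma_max, length.out = n_models)
  out <- vector("list", n_targets)
  for (t in seq_len(n_targets)) {
    tid <- sprintf("T%04d", t)
    native <- make_native(n_residues, fold = folds[(t - 1) %% 4 + 1],
                          seed = seed * 1000 + t, model_id = tid)
    ens <- make_ensemble(native, sigmas, seed = seed * 2000 + t)
    si <- make_sequence_inputs(native, accuracy = accuracy,
                               seed = seed * 3000 + t,
                               dir = if (is.null(dir)) NULL
                                     else file.path(dir, "seqinputs"))
    if (!is.null(dir)) {
      ndir <- file.path(dir, "natives"); mdir <- file.path(dir, "models", tid)
      for (d in c(ndir, mdir)) if (!dir.exists(d)) dir.create(d, recursive = TRUE)
      write_pdb(native, file.path(ndir, paste0(tid, ".pdb")))
      for (m in ens$models)
        write_pdb(m, file.path(mdir, paste0(m$model_id, ".pdb")))
    }
    out[[t]] <- list(target = tid, native = native, models = ens$models,
                     truth_local = cbind(target = tid, ens$truth_local),
                     truth_global = cbind(target = tid, ens$truth_global),
                     seqinputs = si)
  }
  names(out) <- vapply(out, `[[`, character(1), "target")
  if (!is.null(dir)) {
    truth <- do.call(rbind, lapply(out, `[[`, "truth_global"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  out
}
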