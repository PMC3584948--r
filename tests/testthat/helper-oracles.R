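# Independent oracles used across test files. These re-derive quantities by
# the most direct method available (exhaustive pair scans, quaternion
# superposition, rank statistics) and never call the code paths they check.

# build a protein_model from a list of residues:
# list(aa=, atoms=data.frame(elety, x, y, z))
toy_model <- function(residues, model_id = "toy", target_length = NULL) {
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    a <- residues[[i]]$atoms
    a$res_i <- i
    a
  }))
  aa <- vapply(residues, `[[`, character(1), "aa")
  if (is.null(target_length)) target_length <- length(aa)
  protein_model(atoms, aa, model_id = model_id, target_length = target_length)
}

# one residue with backbone placed in a small cluster at `origin` plus
# optionally a CB at an explicit position
toy_residue <- function(aa, origin, cb = NULL) {
  at <- data.frame(elety = c("N", "CA", "C", "O"),
                   x = origin[1] + c(0, 1.46, 2.0, 2.2),
                   y = origin[2] + c(0, 0, 1.2, 2.4),
                   z = origin[3] + c(0, 0, 0, 0),
                   stringsAsFactors = FALSE)
  if (!is.null(cb) && aa != "G")
    at <- rbind(at, data.frame(elety = "CB", x = cb[1], y = cb[2], z = cb[3]))
  list(aa = aa, atoms = at)
}

# exhaustive O(n^2) atom-contact histogram oracle
brute_atom_block <- function(model, center, window = 21, cutoff = 4,
                             min_sep = 2) {
  at <- model$atoms
  half <- (window - 1) %/% 2
  w <- max(1, center - half):min(n_residues(model), center + half)
  M <- matrix(0, 13, 13)
  n <- nrow(at)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(at$res_i[i] - at$res_i[j]) < min_sep) next
    if (!(at$res_i[i] %in% w || at$res_i[j] %in% w)) next
    d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
              (at$z[i] - at$z[j])^2)
    if (d > cutoff) next
    a <- min(at$atom_class[i], at$atom_class[j])
    b <- max(at$atom_class[i], at$atom_class[j])
    M[a, b] <- M[a, b] + 1
  }
  if (sum(M) > 0) M <- M / sum(M)
  M[upper.tri(M, diag = TRUE)]
}

# exhaustive residue-contact oracle (unweighted, one-hot groups)
brute_res_block <- function(model, center, window = 21, cutoff = 6,
                            min_sep = 6) {
  at <- model$atoms[model$atoms$elety == "CA" | model$atoms$is_sidechain, ]
  n <- n_residues(model)
  half <- (window - 1) %/% 2
  w <- max(1, center - half):min(n, center + half)
  g <- assign_residue_group(model$aa)
  M <- matrix(0, 6, 6)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i < min_sep) next
    if (!(i %in% w || j %in% w)) next
    ai <- at[at$res_i == i, ]; aj <- at[at$res_i == j, ]
    if (!nrow(ai) || !nrow(aj)) next
    dmin <- min(sqrt(outer(ai$x, aj$x, "-")^2 + outer(ai$y, aj$y, "-")^2 +
                     outer(ai$z, aj$z, "-")^2))
    if (dmin > cutoff) next
    a <- min(g[i], g[j]); b <- max(g[i], g[j])
    M[a, b] <- M[a, b] + 1
    cnt <- cnt + 1
  }
  if (cnt > 0) M <- M / cnt
  M[upper.tri(M, diag = TRUE)]
}

# Horn quaternion least-squares superposition RMSD (independent of kabsch)
quat_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  S <- t(Pc) %*% Qc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[3, 1] + S[1, 3]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lmax <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  e2 <- (sum(Pc^2) + sum(Qc^2) - 2 * lmax) / nrow(P)
  sqrt(max(0, e2))
}

# Mann-Whitney rank-statistic AUC
rank_auc <- function(scores, positive) {
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# shared small fixture: helix native + perfect-accuracy sequence inputs
shared_fix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      nat <- make_native(30, "helix", seed = 42, model_id = "SFIX")
      si <- make_sequence_inputs(nat, accuracy = 1, seed = 42)
      cache <<- list(native = nat, si = si)
    }
    cache
  }
})
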