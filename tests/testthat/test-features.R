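# Feature extraction: contact histograms vs brute-force oracles, exposure
# binning, agreement windows, profile weighting, global block, invariances

far <- function(k) c(0, 1000 * k, 0)  # park residues far apart

test_that("atom contacts: beyond-cutoff pairs yield an all-zero block", {
  m <- toy_model(list(toy_residue("A", c(0, 0, 0)),
                      toy_residue("A", far(1)),
                      toy_residue("A", far(2)),
                      toy_residue("A", c(0, 0, 4.5), cb = c(1.5, 0, 4.5))))
  expect_equal(sum(atom_contact_features(m, 1)), 0)
})

test_that("a sole CA-CB contact at 3.9 A lands in cell (2,5) with weight 1", {
  # CA (class 2) of residue 1 and CB (class 5) of residue 4, 3.9 A apart,
  # all other atoms out of range; sequence separation 3
  cb4 <- c(1.46, 0, 0) + 3.9 * c(1, -1, 0) / sqrt(2)
  m <- toy_model(list(toy_residue("A", c(0, 0, 0)),
                      toy_residue("A", far(1)),
                      toy_residue("A", far(2)),
                      toy_residue("A", far(3), cb = cb4)))
  block <- atom_contact_features(m, 1)
  M <- matrix(0, 13, 13); M[upper.tri(M, diag = TRUE)] <- block
  expect_equal(M[2, 5], 1)
  expect_equal(sum(block), 1)
  expect_equal(block, brute_atom_block(m, 1))
})

test_that("atom-contact block equals the brute-force pair scan on fixtures", {
  nat <- make_native(25, "two_domain", seed = 13)
  for (center in c(1, 7, 13, 25))
    expect_equal(atom_contact_features(nat, center),
                 brute_atom_block(nat, center), tolerance = 1e-12)
  # histograms sum to 1 (or 0) everywhere
  sums <- vapply(1:25, function(r) sum(atom_contact_features(nat, r)),
                 numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
})

test_that("residue contacts respect the >5 separation rule and group cells", {
  mk <- function(sep) {
    res <- c(list(toy_residue("R", c(0, 0, 0))),
             lapply(seq_len(sep - 1), function(k) toy_residue("A", far(k))),
             list(toy_residue("E", c(5, 0, 0))))
    toy_model(res)
  }
  m9 <- mk(8)  # separation 8: CA-CA distance 5 A
  block <- residue_contact_features(m9, 1)
  M <- matrix(0, 6, 6); M[upper.tri(M, diag = TRUE)] <- block
  expect_equal(M[1, 2], 1)   # Arg group 1, Glu group 2
  expect_equal(block, brute_res_block(m9, 1))
  m5 <- mk(4)  # separation 4: excluded
  expect_equal(sum(residue_contact_features(m5, 1)), 0)
})

test_that("residue-contact block matches the brute-force oracle on fixtures", {
  nat <- make_native(30, "coil", seed = 21)
  for (center in c(1, 10, 20, 30))
    expect_equal(residue_contact_features(nat, center),
                 brute_res_block(nat, center), tolerance = 1e-12)
})

test_that("profile weighting distributes contact mass by frequency", {
  res <- c(list(toy_residue("R", c(0, 0, 0))),
           lapply(1:7, function(k) toy_residue("A", far(k))),
           list(toy_residue("A", c(5, 0, 0))))
  m <- toy_model(res)
  freqs <- matrix(0, 9, 20, dimnames = list(NULL, proqr:::PSSM_AA_ORDER))
  freqs[cbind(1:9, match(m$aa, colnames(freqs)))] <- 1
  freqs[9, ] <- 0; freqs[9, "A"] <- 0.4; freqs[9, "S"] <- 0.6
  prof <- structure(list(length = 9, query = m$aa, freqs = freqs,
                         pssm = freqs, ipp = rep(1, 9)),
                    class = "sequence_profile")
  block <- residue_contact_features(m, 1, profile = prof)
  M <- matrix(0, 6, 6); M[upper.tri(M, diag = TRUE)] <- block
  expect_equal(M[1, 5], 0.4)  # 40% contact to Ala (group 5)
  expect_equal(M[1, 4], 0.6)  # 60% contact to Ser (group 4)
  expect_equal(sum(block), 1)
})

test_that("exposure features bin by group with left-closed boundaries", {
  m <- toy_model(list(toy_residue("R", c(0, 0, 0), cb = c(1.5, 1, 0))))
  b <- exposure_features(m, 1, sasa = 0.30, window = 1)
  M <- matrix(b, 6, 4)
  expect_equal(M[1, 2], 1)  # group 1 (Arg), bin 2 (25-50%)
  expect_equal(sum(b), 1)
  # boundary value 0.25 opens the 25-50% bin
  b25 <- matrix(exposure_features(m, 1, sasa = 0.25, window = 1), 6, 4)
  expect_equal(b25[1, 2], 1)
  b24 <- matrix(exposure_features(m, 1, sasa = 0.2499, window = 1), 6, 4)
  expect_equal(b24[1, 1], 1)
})

test_that("exposure block with a uniform profile is the mean of pure blocks", {
  m <- toy_model(list(toy_residue("R", c(0, 0, 0), cb = c(1.5, 1, 0)),
                      toy_residue("D", c(8, 0, 0), cb = c(9.5, 1, 0)),
                      toy_residue("G", c(16, 0, 0))))
  sasa <- c(0.1, 0.4, 0.9)
  unif <- structure(list(length = 3, query = m$aa,
                         freqs = matrix(1 / 20, 3, 20,
                                        dimnames = list(NULL, proqr:::PSSM_AA_ORDER)),
                         pssm = NULL, ipp = rep(1, 3)),
                    class = "sequence_profile")
  got <- exposure_features(m, 2, sasa, profile = unif, window = 21)
  pure <- lapply(proqr:::PSSM_AA_ORDER, function(aa) {
    m2 <- m; m2$aa <- rep(aa, 3)
    exposure_features(m2, 2, sasa, window = 21)
  })
  expect_equal(got, Reduce(`+`, pure) / 20, tolerance = 1e-12)
})

test_that("secondary-structure agreement features and truncation rule", {
  fix <- shared_fix()
  nat <- fix$native; si <- fix$si
  assigned <- si$assigned_ss
  f <- ss_agreement_features(assigned, si$ss_pred, nat, 15)
  expect_equal(f$agree, 1)           # accuracy-1 inputs agree everywhere
  expect_length(f$central, 3)
  expect_equal(sum(f$onehot), 5)     # interior window: 5 one-hot positions
  # prediction disagreeing everywhere
  bad <- si$ss_pred
  wrong <- ifelse(assigned == "H", "E", "H")
  bad$class <- wrong
  expect_equal(ss_agreement_features(assigned, bad, nat, 15)$agree, 0)
  # center 2 of a 10-residue model: denominator is the 10 real residues
  nat10 <- make_native(10, "helix", seed = 2, model_id = "S10")
  si10 <- make_sequence_inputs(nat10, accuracy = 1, seed = 2)
  half_right <- si10$ss_pred
  half_right$class <- si10$assigned_ss
  half_right$class[6:10] <- ifelse(si10$assigned_ss[6:10] == "H", "E", "H")
  f10 <- ss_agreement_features(si10$assigned_ss, half_right, nat10, 2)
  expect_equal(f10$agree, 5 / 10)
  # terminal 5-window is truncated, absent positions all-zero
  fterm <- ss_agreement_features(assigned, si$ss_pred, nat, 1)
  expect_equal(sum(fterm$onehot), 3)
})

test_that("surface agreement and windowed area features", {
  fix <- shared_fix()
  nat <- fix$native; si <- fix$si
  n <- n_residues(nat)
  all_b <- si$exp_pred; all_b$class <- rep("b", n)
  f <- surface_agreement_features(rep(0.1, n), all_b, nat, 10)
  expect_equal(f$agree, 1)
  f2 <- surface_agreement_features(rep(0.5, n), all_b, nat, 10)
  expect_equal(f2$agree, 0)      # all exposed but predicted buried
  expect_equal(f2$area, 0.5)     # w13 mean of constant exposures
  # random fixture equals an independent recomputation
  set.seed(7)
  sasa <- runif(n)
  pred <- si$exp_pred; pred$class <- sample(c("b", "e"), n, replace = TRUE)
  got <- surface_agreement_features(sasa, pred, nat, 12)
  w <- 2:22  # 21-window at center 12 in a 30-residue model
  expect_equal(got$agree,
               mean((sasa[w] < 0.25) == (pred$class[nat$target_pos[w]] == "b")))
  expect_equal(got$area, mean(sasa[6:18]))
})

test_that("IPP feature averages a 3-window with terminus truncation", {
  fix <- shared_fix()
  prof <- fix$si$profile
  prof$ipp <- rep(1.2, 30)
  expect_equal(ipp_feature(prof, fix$native, 15), 1.2)
  prof$ipp <- seq_len(30) / 10
  expect_equal(ipp_feature(prof, fix$native, 1), mean(c(0.1, 0.2)))
  expect_equal(ipp_feature(prof, fix$native, 15), mean(c(1.4, 1.5, 1.6)))
})

test_that("global agreements match windowed values for short models", {
  nat <- make_native(20, "helix", seed = 31, model_id = "G20")
  si <- make_sequence_inputs(nat, accuracy = 1, seed = 3)
  g <- global_features(nat, si$sasa, si$assigned_ss, si$ss_pred, si$exp_pred)
  expect_equal(unname(g), c(1, 1))
  # global value equals the w21 agreement when the model fits in one window
  f <- ss_agreement_features(si$assigned_ss, si$ss_pred, nat, 10)
  expect_equal(unname(g["ss_agree"]), f$agree)
  s <- surface_agreement_features(si$sasa, si$exp_pred, nat, 10)
  expect_equal(unname(g["surf_agree"]), s$agree)
  # half-agreement counts directly
  half <- si$ss_pred
  half$class <- si$assigned_ss
  half$class[1:10] <- ifelse(si$assigned_ss[1:10] == "C", "H", "C")
  g2 <- global_features(nat, si$sasa, si$assigned_ss, half, si$exp_pred)
  expect_equal(unname(g2["ss_agree"]), 0.5)
})

test_that("feature vectors have fixed length, shared global block, and are deterministic", {
  fix <- shared_fix()
  f <- model_features(fix$native, fix$si$profile, fix$si$ss_pred,
                      fix$si$exp_pred)
  expect_equal(dim(f), c(30, 160))
  expect_equal(colnames(f), feature_names())
  expect_length(unique(f[, "global_ss_agree"]), 1)
  expect_length(unique(f[, "global_surf_agree"]), 1)
  f2 <- model_features(fix$native, fix$si$profile, fix$si$ss_pred,
                       fix$si$exp_pred)
  expect_identical(f, f2)
})

test_that("a one-hot profile on the model sequence reproduces unweighted blocks", {
  fix <- shared_fix()
  nat <- fix$native
  onehot <- fix$si$profile
  onehot$freqs[] <- 0
  onehot$freqs[cbind(1:30, match(nat$aa, colnames(onehot$freqs)))] <- 1
  for (center in c(5, 15)) {
    expect_equal(residue_contact_features(nat, center, profile = onehot),
                 residue_contact_features(nat, center, profile = NULL),
                 tolerance = 1e-12)
    expect_equal(exposure_features(nat, center, fix$si$sasa, profile = onehot),
                 exposure_features(nat, center, fix$si$sasa, profile = NULL),
                 tolerance = 1e-12)
  }
})

test_that("features are invariant along the chain and under rigid motion", {
  nat <- make_native(40, "helix", sequence = rep("L", 40), seed = 1,
                     model_id = "PERIODIC")
  si <- make_sequence_inputs(nat, accuracy = 1, seed = 1)
  f <- model_features(nat, si$profile, si$ss_pred, si$exp_pred)
  expect_equal(f[18, ], f[21, ], tolerance = 0.02)
  # rigid motion: rotate + translate every atom
  ang <- 0.9
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  rot <- nat
  rot$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(nat$atoms[, c("x", "y", "z")]) %*% t(R), 2, c(5, -3, 11), "+")
  frot <- model_features(rot, si$profile, si$ss_pred, si$exp_pred)
  expect_equal(frot[, 1:112], f[, 1:112], tolerance = 1e-9)  # contacts exact
  expect_equal(frot, f, tolerance = 0.02)                    # SASA numerical
})

test_that("SASA: isolated residue fully exposed, buried core occluded", {
  # a side chain with no occlusion at all reaches the reference area
  iso <- toy_model(list(toy_residue("A", c(0, 0, 0), cb = c(12, 0, 0))))
  expect_equal(compute_sasa(iso), 1)
  # an Ala in an extended tripeptide stays clearly on the exposed side
  tri <- make_native(3, "sheet", sequence = c("G", "A", "G"), seed = 1)
  expect_gt(compute_sasa(tri)[2], 0.5)
  # central residue inside a 3x3x3 grid of neighbours is buried
  grid <- expand.grid(x = c(-5, 0, 5), y = c(-5, 0, 5), z = c(-5, 0, 5))
  grid <- grid[order(-(grid$x == 0 & grid$y == 0 & grid$z == 0)), ]
  res <- lapply(seq_len(27), function(i)
    toy_residue("V", as.numeric(grid[i, ]),
                cb = as.numeric(grid[i, ]) + c(1.5, 1, 0)))
  m <- toy_model(res)
  expect_lt(compute_sasa(m)[1], 0.25)
})

test_that("SASA converges: doubling the sphere points changes areas < 2%", {
  nat <- make_native(10, "helix", seed = 17)
  at <- nat$atoms
  a1 <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]), at$element,
                      n_points = 960)
  a2 <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]), at$element,
                      n_points = 1920)
  per_res1 <- tapply(a1, at$res_i, sum)
  per_res2 <- tapply(a2, at$res_i, sum)
  expect_true(all(abs(per_res1 - per_res2) / pmax(per_res2, 1) < 0.02))
})

test_that("secondary-structure assignment follows dihedral rules and readers map codes", {
  helix <- make_native(20, "helix", sequence = rep("A", 20), seed = 1)
  ss <- assign_secondary_structure(helix)
  expect_true(all(ss[3:18] == "H"))
  ext <- make_native(20, "sheet", seed = 1)
  expect_false(any(assign_secondary_structure(ext) == "H"))
  # STRIDE reader: one-letter codes mapped {H,G,I}->H, {E,B}->E, else C
  f <- withr::local_tempfile()
  asg <- function(code) sprintf("ASG  ALA A    1    1    %s   Helix", code)
  writeLines(vapply(c("H", "G", "I", "E", "B", "T", "C"), asg, ""), f)
  expect_equal(read_stride(f), c("H", "H", "H", "E", "E", "C", "C"))
})
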