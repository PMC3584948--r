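# S-score target function, superposition, GDT_TS

test_that("S-score hits its closed-form anchors and rejects bad input", {
  expect_equal(s_score(3, d0 = 3), 0.5)
  expect_equal(s_score(0), 1)
  expect_equal(s_score(9, d0 = 3), 0.1)
  expect_error(s_score(-1), "non-negative")
  expect_error(s_score(1, d0 = 0), "positive")
  d <- seq(0, 20, by = 0.5)
  expect_true(all(diff(s_score(d)) < 0))  # strictly decreasing
})

test_that("s_to_distance is the exact inverse of s_score", {
  expect_equal(s_to_distance(0.5), 3)
  expect_equal(s_to_distance(1), 0)
  expect_equal(s_to_distance(0.1), 9)
  expect_error(s_to_distance(0), "\\(0,1\\]")
  expect_error(s_to_distance(1.2), "\\(0,1\\]")
  d <- c(0, 0.3, 1, 2.5, 3, 7, 19)
  expect_equal(s_to_distance(s_score(d)), d, tolerance = 1e-9)
  s <- c(1e-4, 0.25, 0.5, 0.99, 1)
  expect_equal(s_score(s_to_distance(s)), s, tolerance = 1e-9)
})

test_that("kabsch recovers identity, known rotations, and quaternion RMSD", {
  set.seed(5)
  P <- matrix(rnorm(30), 10, 3)
  k0 <- kabsch(P, P)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(k0$translation, rep(0, 3), tolerance = 1e-9)
  expect_equal(k0$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(k0$rotation), 1, tolerance = 1e-9)
  # recover a constructed rotation
  ang <- 1.1
  R0 <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0, -sin(ang), 0, cos(ang)),
               3, 3, byrow = TRUE)
  Q <- t(R0 %*% t(P)) + matrix(c(3, -2, 7), 10, 3, byrow = TRUE)
  k <- kabsch(P, Q)
  expect_equal(k$rotation, R0, tolerance = 1e-6)
  expect_equal(k$rmsd, 0, tolerance = 1e-6)
  # RMSD equals the independent quaternion solution on random pairs
  for (i in 1:5) {
    A <- matrix(rnorm(30), 10, 3)
    B <- matrix(rnorm(30), 10, 3)
    expect_equal(kabsch(A, B)$rmsd, quat_rmsd(A, B), tolerance = 1e-9)
  }
  expect_error(kabsch(P[1:2, ], P[1:2, ]), "at least 3")
})

test_that("optimal superposition: identical models score N, outliers drop out", {
  nat <- make_native(30, "two_domain", seed = 3)
  r <- optimal_s_superposition(nat, nat)
  expect_equal(r$sum_s, 30)
  expect_true(all(r$local$s == 1))
  # displace one residue 30 A
  pert <- nat
  sel <- pert$atoms$res_i == 15
  pert$atoms$x[sel] <- pert$atoms$x[sel] + 30
  rp <- optimal_s_superposition(pert, nat)
  expect_lt(rp$local$s[15], 0.01)
  expect_true(all(rp$local$s[-15] > 0.95))
})

test_that("superposition sum is rigid-motion invariant and dominates plain Kabsch", {
  nat <- make_native(40, "two_domain", seed = 11)
  ens <- make_ensemble(nat, sigmas = c(1.5), seed = 4)
  mod <- ens$models[[1]]
  base <- optimal_s_superposition(mod, nat)
  # rigid motion of the model
  ang <- 0.6
  R <- matrix(c(1, 0, 0, 0, cos(ang), -sin(ang), 0, sin(ang), cos(ang)),
              3, 3, byrow = TRUE)
  moved <- mod
  moved$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(mod$atoms[, c("x", "y", "z")]) %*% t(R), 2, c(1, 2, 3), "+")
  expect_equal(optimal_s_superposition(moved, nat)$sum_s, base$sum_s,
               tolerance = 1e-6)
  # dominance over the all-residue least-squares fit
  k <- kabsch(ca_coords(mod), ca_coords(nat))
  d <- sqrt(rowSums((transform_coords(ca_coords(mod), k) - ca_coords(nat))^2))
  expect_gte(base$sum_s, sum(s_score(d)) - 1e-9)
})

test_that("two-domain fit is at least as good as a single-domain fit", {
  nat <- make_native(40, "two_domain", seed = 8)
  # rotate the second half away
  mod <- nat
  sel <- mod$atoms$res_i > 20
  xyz <- as.matrix(mod$atoms[sel, c("x", "y", "z")])
  ang <- pi / 2
  R <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  pivot <- colMeans(xyz)
  mod$atoms[sel, c("x", "y", "z")] <-
    sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, "+")
  res <- optimal_s_superposition(mod, nat)
  # lower bound: superpose on the intact first domain only
  k <- kabsch(ca_coords(mod), ca_coords(nat), subset = 1:20)
  d <- sqrt(rowSums((transform_coords(ca_coords(mod), k) - ca_coords(nat))^2))
  expect_gte(res$sum_s, sum(s_score(d)) - 1e-9)
  expect_gte(res$sum_s, 19)  # the matching 20-residue domain fits
})

test_that("mean S decreases monotonically with perturbation scale", {
  nat <- make_native(35, "helix", seed = 2)
  ens <- make_ensemble(nat, sigmas = c(0, 1, 3, 6, 12), seed = 19)
  means <- tapply(ens$truth_local$s, ens$truth_local$model_id, mean)
  means <- means[unique(ens$truth_local$model_id)]
  expect_true(all(diff(unname(means)) < 0))
})

test_that("GDT_TS: identity and rigid translation give 100, half-off gives ~50", {
  nat <- make_native(24, "two_domain", seed = 6)
  expect_equal(gdt_ts(nat, nat), 100)
  shifted <- nat
  shifted$atoms$x <- shifted$atoms$x + 10
  expect_equal(gdt_ts(shifted, nat), 100)
  # half the residues exact, half >= 20 A off in scattered directions
  mod <- nat
  sel <- mod$atoms$res_i > 12
  set.seed(99)
  offs <- matrix(rnorm(12 * 3), 12, 3)
  offs <- offs / sqrt(rowSums(offs^2)) * runif(12, 25, 60)
  mod$atoms[sel, c("x", "y", "z")] <-
    as.matrix(mod$atoms[sel, c("x", "y", "z")]) + offs[mod$atoms$res_i[sel] - 12, ]
  g <- gdt_ts(mod, nat)
  expect_gt(g, 40); expect_lt(g, 60)
  # dominance over any single fixed superposition (all-residue Kabsch)
  k <- kabsch(ca_coords(mod), ca_coords(nat))
  d <- sqrt(rowSums((transform_coords(ca_coords(mod), k) - ca_coords(nat))^2))
  fixed_gdt <- 100 * mean(vapply(c(1, 2, 4, 8), function(t) mean(d <= t),
                                 numeric(1)))
  expect_gte(g, fixed_gdt - 1e-9)
})
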