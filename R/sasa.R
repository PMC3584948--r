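# Numerical solvent-accessible surface area (Shrake-Rupley) and per-residue
# relative side-chain exposure.

# van der Waals radii (A) by element
.VDW <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Maximum side-chain accessible areas (A^2), Miller et al. (1987) tripeptide
# values; Gly uses the backbone-inclusive total. Swappable via the
# `ref_areas` argument of compute_sasa().
MAX_SIDECHAIN_AREA <- c(
  A = 67,  R = 196, N = 113, D = 106, C = 104,
  Q = 144, E = 138, G = 84,  H = 151, I = 140,
  L = 137, K = 167, M = 160, F = 175, P = 105,
  S = 80,  T = 102, W = 217, Y = 187, V = 117)

# deterministic quasi-uniform points on the unit sphere (golden spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's solvent-extended sphere (vdW radius + probe)
#' is sampled with a deterministic quasi-uniform point set; the accessible
#' area is the fraction of points not inside any neighbouring atom's
#' extended sphere.
#'
#' @param coords n x 3 matrix of heavy-atom coordinates (Angstrom).
#' @param elements character vector of elements (C/N/O/S).
#' @param probe probe radius in Angstrom (water = 1.4).
#' @param n_points sphere sample points per atom; accuracy grows with count.
#' @return numeric vector of per-atom areas in square Angstrom.
#' @export
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  radii <- .VDW[elements]
  if (anyNA(radii)) stop("unknown element(s): ",
                         paste(unique(elements[is.na(radii)]), collapse = ","))
  r_ext <- radii + probe
  pts <- .sphere_points(n_points)
  area <- numeric(n)
  max_reach <- 2 * max(r_ext)
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2 < (r_ext[i] + r_ext)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * r_ext[i]^2
      next
    }
    sp <- pts * r_ext[i]
    sp <- sweep(sp, 2, coords[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
            (sp[, 3] - coords[j, 3])^2
      free <- free & (dj > r_ext[j]^2)
      if (!any(free)) break
    }
    area[i] <- 4 * pi * r_ext[i]^2 * sum(free) / n_points
  }
  area
}

#' Relative side-chain solvent exposure per residue
#'
#' SASA of each residue's side-chain atoms (Gly: backbone atoms) divided by
#' a per-residue-type maximum reference area, clamped to [0,1]. Residues
#' whose side chain is truncated in the model contribute the atoms present.
#'
#' @param model a \code{protein_model}.
#' @param probe probe radius (Angstrom).
#' @param n_points sphere points per atom.
#' @param ref_areas named vector of maximum areas per one-letter code.
#' @return numeric vector, one relative exposure in [0,1] per residue.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960,
                         ref_areas = MAX_SIDECHAIN_AREA) {
  at <- model$atoms
  area <- shrake_rupley(as.matrix(at[, c("x", "y", "z")]), at$element,
                        probe = probe, n_points = n_points)
  n <- n_residues(model)
  rel <- numeric(n)
  for (r in seq_len(n)) {
    sel <- at$res_i == r & (at$is_sidechain | model$aa[r] == "G")
    if (!any(sel)) sel <- at$res_i == r   # side chain fully absent: backbone
    rel[r] <- min(1, sum(area[sel]) / ref_areas[[model$aa[r]]])
  }
  rel
}
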