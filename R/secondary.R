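# Three-state secondary-structure assignment from backbone geometry, plus
# readers for external STRIDE / DSSP assignments.

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedral angles of a model
#'
#' @param model a \code{protein_model} with N/CA/C backbone atoms.
#' @return matrix n x 2 (phi, psi) in degrees; NA at chain termini or where
#'   backbone atoms are missing.
#' @export
backbone_dihedrals <- function(model) {
  n <- n_residues(model)
  get <- function(r, name) {
    a <- model$atoms[model$atoms$res_i == r & model$atoms$elety == name, ]
    if (nrow(a) != 1) return(NULL)
    c(a$x, a$y, a$z)
  }
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("phi", "psi")))
  for (r in seq_len(n)) {
    Nr <- get(r, "N"); CAr <- get(r, "CA"); Cr <- get(r, "C")
    if (is.null(Nr) || is.null(CAr) || is.null(Cr)) next
    if (r > 1) {
      Cp <- get(r - 1, "C")
      if (!is.null(Cp)) out[r, 1] <- .dihedral(Cp, Nr, CAr, Cr)
    }
    if (r < n) {
      Nn <- get(r + 1, "N")
      if (!is.null(Nn)) out[r, 2] <- .dihedral(Nr, CAr, Cr, Nn)
    }
  }
  out
}

#' Assign three-state secondary structure from backbone dihedrals
#'
#' A dihedral-rule assigner: residues in the alpha region of the
#' Ramachandran map (phi in [-100,-30], psi in [-80,-5]) are helix, residues
#' in the beta region (phi in [-180,-45], psi in [90,180] or below -150) are
#' strand, everything else coil. Helix runs shorter than 4 and strand runs
#' shorter than 2 are relabelled coil; termini (undefined dihedrals) are
#' coil.
#'
#' @param model a \code{protein_model}.
#' @return character vector over residues, values "H", "E" or "C".
#' @export
assign_secondary_structure <- function(model) {
  di <- backbone_dihedrals(model)
  phi <- di[, 1]; psi <- di[, 2]
  cls <- rep("C", nrow(di))
  h <- !is.na(phi) & !is.na(psi) &
    phi >= -100 & phi <= -30 & psi >= -80 & psi <= -5
  e <- !is.na(phi) & !is.na(psi) & !h &
    phi >= -180 & phi <= -45 & (psi >= 90 | psi <= -150)
  cls[h] <- "H"; cls[e] <- "E"
  cls <- .min_run(cls, "H", 4)
  cls <- .min_run(cls, "E", 2)
  cls
}

.min_run <- function(cls, state, min_len) {
  r <- rle(cls)
  short <- r$values == state & r$lengths < min_len
  r$values[short] <- "C"
  inverse.rle(r)
}

#' Read a STRIDE secondary-structure assignment file
#'
#' Parses ASG records and maps the one-letter assignment onto three states:
#' H/G/I to helix, E/B/b to strand, everything else coil.
#'
#' @param path STRIDE output file (-f format).
#' @return character vector of "H"/"E"/"C" in record order.
#' @export
read_stride <- function(path) {
  lines <- grep("^ASG", readLines(path), value = TRUE)
  if (!length(lines)) stop("no ASG records in ", path)
  code <- toupper(substr(lines, 25, 25))
  .map_ss8(code)
}

#' Read a DSSP file into three-state secondary structure
#'
#' @param path DSSP output file.
#' @return character vector of "H"/"E"/"C" in record order.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (!length(start)) stop("no DSSP data header in ", path)
  body <- lines[(start + 1):length(lines)]
  body <- body[substr(body, 14, 14) != "!"]
  .map_ss8(toupper(substr(body, 17, 17)))
}

.map_ss8 <- function(code) {
  out <- rep("C", length(code))
  out[code %in% c("H", "G", "I")] <- "H"
  out[code %in% c("E", "B")] <- "E"
  out
}
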