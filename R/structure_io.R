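#' @keywords internal
"_PACKAGE"

# Three-letter <-> one-letter amino-acid tables -------------------------------

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
AA1 <- stats::setNames(names(AA3), AA3)

#' Residue groups used for residue-residue contact and exposure features
#'
#' The twenty standard amino acids are partitioned into six physico-chemical
#' groups: (1) positively charged Arg/Lys, (2) negatively charged Asp/Glu,
#' (3) aromatic His/Phe/Trp/Tyr, (4) polar Asn/Gln/Ser/Thr,
#' (5) hydrophobic Ala/Ile/Leu/Met/Val/Cys, (6) conformationally special
#' Gly/Pro.
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @return integer vector of group indices in 1..6.
#' @examples
#' assign_residue_group(c("R", "G"))
#' @export
assign_residue_group <- function(aa) {
  groups <- c(R = 1L, K = 1L,
              D = 2L, E = 2L,
              H = 3L, F = 3L, W = 3L, Y = 3L,
              N = 4L, Q = 4L, S = 4L, T = 4L,
              A = 5L, I = 5L, L = 5L, M = 5L, V = 5L, C = 5L,
              G = 6L, P = 6L)
  out <- groups[toupper(aa)]
  if (anyNA(out))
    stop("cannot assign residue group for code(s): ",
         paste(unique(aa[is.na(out)]), collapse = ", "))
  unname(out)
}

# 13 atom types. Backbone atoms class identically across residues; side-chain
# atoms are classed by chemistry. Single source of truth for the whole package.
#   1 backbone N          2 backbone CA        3 carbonyl/sp2-polar C
#   4 backbone O (+OXT)   5 CB                 6 aliphatic side-chain C
#   7 aromatic C          8 polar side-chain N (amide/guanidinium/amine)
#   9 aromatic ring N    10 hydroxyl O        11 carboxylate O
#  12 amide O            13 sulfur
.SIDECHAIN_CLASS <- list(
  A = c(CB = 5),
  R = c(CB = 5, CG = 6, CD = 6, NE = 8, CZ = 3, NH1 = 8, NH2 = 8),
  N = c(CB = 5, CG = 3, OD1 = 12, ND2 = 8),
  D = c(CB = 5, CG = 3, OD1 = 11, OD2 = 11),
  C = c(CB = 5, SG = 13),
  Q = c(CB = 5, CG = 6, CD = 3, OE1 = 12, NE2 = 8),
  E = c(CB = 5, CG = 6, CD = 3, OE1 = 11, OE2 = 11),
  G = c(),
  H = c(CB = 5, CG = 7, ND1 = 9, CD2 = 7, CE1 = 7, NE2 = 9),
  I = c(CB = 5, CG1 = 6, CG2 = 6, CD1 = 6),
  L = c(CB = 5, CG = 6, CD1 = 6, CD2 = 6),
  K = c(CB = 5, CG = 6, CD = 6, CE = 6, NZ = 8),
  M = c(CB = 5, CG = 6, SD = 13, CE = 6),
  F = c(CB = 5, CG = 7, CD1 = 7, CD2 = 7, CE1 = 7, CE2 = 7, CZ = 7),
  P = c(CB = 5, CG = 6, CD = 6),
  S = c(CB = 5, OG = 10),
  T = c(CB = 5, OG1 = 10, CG2 = 6),
  W = c(CB = 5, CG = 7, CD1 = 7, CD2 = 7, NE1 = 9, CE2 = 7, CE3 = 7,
        CZ2 = 7, CZ3 = 7, CH2 = 7),
  Y = c(CB = 5, CG = 7, CD1 = 7, CD2 = 7, CE1 = 7, CE2 = 7, CZ = 7,
        OH = 10),
  V = c(CB = 5, CG1 = 6, CG2 = 6)
)
.BACKBONE_CLASS <- c(N = 1, CA = 2, C = 3, O = 4, OXT = 4)

#' Atom-type classification (13 classes) for contact features
#'
#' Heavy atoms of the twenty standard residues are mapped onto 13 chemical
#' classes (backbone N/CA/C/O, CB, aliphatic C, sp2-polar C, aromatic C,
#' polar N, aromatic N, hydroxyl O, carboxylate O, amide O, S). Backbone
#' atoms are classed identically in every residue type.
#'
#' @param aa one-letter residue code(s).
#' @param atom_name PDB atom name(s), e.g. "CA", "SG".
#' @return integer vector of atom classes in 1..13.
#' @export
assign_atom_class <- function(aa, atom_name) {
  aa <- toupper(aa); atom_name <- toupper(atom_name)
  n <- max(length(aa), length(atom_name))
  aa <- rep_len(aa, n); atom_name <- rep_len(atom_name, n)
  out <- integer(n)
  bb <- atom_name %in% names(.BACKBONE_CLASS)
  out[bb] <- .BACKBONE_CLASS[atom_name[bb]]
  for (i in which(!bb)) {
    sc <- .SIDECHAIN_CLASS[[aa[i]]]
    if (is.null(sc) || !(atom_name[i] %in% names(sc)))
      stop("unknown heavy atom '", atom_name[i], "' for residue ", aa[i])
    out[i] <- sc[[atom_name[i]]]
  }
  as.integer(out)
}

#' Table of every standard heavy atom with its atom class
#'
#' @return data.frame with columns aa, atom, class covering all heavy atoms
#'   of the 20 standard residues.
#' @export
atom_class_table <- function() {
  rows <- lapply(names(.SIDECHAIN_CLASS), function(aa) {
    sc <- .SIDECHAIN_CLASS[[aa]]
    atoms <- c(names(.BACKBONE_CLASS)[1:4], names(sc))
    data.frame(aa = aa, atom = atoms,
               class = assign_atom_class(aa, atoms),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.element_of <- function(atom_name) substr(gsub("[0-9]", "", atom_name), 1, 1)

#' Construct a protein model object
#'
#' The core container: an ordered set of residues with heavy-atom
#' coordinates, a one-letter sequence and a mapping of each modeled residue
#' to a position in the (possibly longer) target sequence.
#'
#' @param atoms data.frame with columns res_i (1-based residue index into the
#'   model), elety (atom name), x, y, z.
#' @param aa one-letter sequence of the modeled residues.
#' @param model_id identifier string.
#' @param target_pos integer vector, target position (1-based) of each
#'   modeled residue; defaults to sequential.
#' @param target_length length of the target sequence; defaults to
#'   max(target_pos).
#' @return object of class \code{protein_model}.
#' @export
protein_model <- function(atoms, aa, model_id = "model",
                          target_pos = seq_along(aa),
                          target_length = max(target_pos)) {
  stopifnot(is.data.frame(atoms),
            all(c("res_i", "elety", "x", "y", "z") %in% names(atoms)))
  n <- length(aa)
  if (n == 0L) stop("empty model: no residues")
  if (length(target_pos) != n) stop("target_pos length != residue count")
  if (any(diff(target_pos) <= 0)) stop("residues must be ordered by target position")
  if (target_length < n) stop("target_length smaller than number of residues")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  atoms$elety <- toupper(atoms$elety)
  atoms$element <- .element_of(atoms$elety)
  atoms$atom_class <- assign_atom_class(aa[atoms$res_i], atoms$elety)
  atoms$is_sidechain <- !(atoms$elety %in% c("N", "CA", "C", "O", "OXT"))
  structure(list(model_id = model_id, atoms = atoms, aa = aa,
                 target_pos = as.integer(target_pos),
                 target_length = as.integer(target_length)),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("<protein_model> %s: %d residues (%d atoms), target length %d\n",
              x$model_id, length(x$aa), nrow(x$atoms), x$target_length))
  invisible(x)
}

#' Number of modeled residues
#' @param model a \code{protein_model}.
#' @export
n_residues <- function(model) length(model$aa)

#' C-alpha coordinate matrix of a model
#'
#' @param model a \code{protein_model}.
#' @return numeric matrix n_residues x 3; rows are NA where CA is absent.
#' @export
ca_coords <- function(model) {
  out <- matrix(NA_real_, n_residues(model), 3)
  ca <- model$atoms[model$atoms$elety == "CA", ]
  out[ca$res_i, ] <- as.matrix(ca[, c("x", "y", "z")])
  out
}

#' Read a protein model from a PDB file
#'
#' Parses ATOM records (first chain by default), drops hydrogens, HETATM
#' records and alternate locations (keeping the highest-occupancy copy), and
#' builds a \code{protein_model}. Residue order follows the chain; the
#' target mapping defaults to sequential numbering unless an alignment is
#' given.
#'
#' @param path PDB file.
#' @param model_id identifier; defaults to the file name.
#' @param chain chain identifier to keep; default the first chain found.
#' @param target_alignment optional integer vector mapping each modeled
#'   residue (in chain order) to a 1-based target position.
#' @param target_length optional target sequence length.
#' @return a \code{protein_model}.
#' @export
read_pdb <- function(path, model_id = NULL, chain = NULL,
                     target_alignment = NULL, target_length = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  at <- at[at$resid %in% names(AA3), , drop = FALSE]
  at <- at[.element_of(at$elety) != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty model: no standard ATOM records in ", path)
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records for chain ", chain, " in ", path)
  # resolve altlocs: keep highest occupancy per (residue, atom name),
  # preserving file order
  ins <- ifelse(is.na(at$insert), "", at$insert)
  reskey <- paste(at$resno, ins, sep = "_")
  occ <- ifelse(is.na(at$o), 1, at$o)
  akey <- paste(reskey, at$elety)
  best <- tapply(seq_len(nrow(at)), akey, function(i) i[which.max(occ[i])])
  keep <- sort(unlist(best))
  at <- at[keep, , drop = FALSE]
  reskey <- reskey[keep]
  res_i <- match(reskey, unique(reskey))
  aa <- AA3[at$resid[!duplicated(res_i)]]
  atoms <- data.frame(res_i = res_i, elety = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  n <- length(aa)
  tp <- if (!is.null(target_alignment)) target_alignment else seq_len(n)
  tl <- if (!is.null(target_length)) target_length else max(tp)
  if (is.null(model_id))
    model_id <- sub("\\.(pdb|ent)$", "", basename(path))
  protein_model(atoms, unname(aa), model_id = model_id,
                target_pos = tp, target_length = tl)
}

#' Write a protein model to a PDB file
#'
#' @param model a \code{protein_model}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pdb <- function(model, path) {
  at <- model$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = at$res_i, resid = AA1[model$aa[at$res_i]],
                   eleno = seq_len(nrow(at)), elety = at$elety,
                   chain = rep("A", nrow(at)))
  invisible(path)
}

#' Sequence of a model as a one-letter string
#' @param model a \code{protein_model}.
#' @export
model_sequence <- function(model) paste(model$aa, collapse = "")
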