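# Readers for sequence-derived prediction files: PSI-BLAST ASCII PSSM,
# PSIPRED .ss2 secondary-structure prediction and a two-line burial/exposure
# prediction. Matching writers live in fixtures.R; each reader is the exact
# inverse of its writer on generated files.

PSSM_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the "-Q" ASCII dialect: a header, then one row per target position
#' with the query residue, 20 log-odds scores, 20 weighted observed
#' percentages and the information-per-position column. Profile frequencies
#' are taken from the percentage columns rescaled to sum to one; an all-zero
#' percentage row falls back to a one-hot profile on the query residue.
#'
#' @param path PSSM file.
#' @return a \code{sequence_profile}: list with \code{length}, \code{query}
#'   (one-letter vector), \code{freqs} (n x 20 matrix, rows on the
#'   probability simplex, columns in PSI-BLAST amino-acid order),
#'   \code{pssm} (n x 20 log-odds) and \code{ipp} (information per position,
#'   bits).
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  toks <- lapply(lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  is_row <- vapply(toks, function(tk)
    length(tk) >= 43 && grepl("^[0-9]+$", tk[1]) && tk[2] %in% PSSM_AA_ORDER,
    logical(1))
  if (!any(is_row)) stop("no PSSM rows found in ", path)
  rows <- toks[is_row]
  bad <- which(vapply(rows, length, integer(1)) < 44)
  if (length(bad))
    stop("PSSM format error at line ", which(is_row)[bad[1]],
         ": expected 44 columns")
  n <- length(rows)
  query <- vapply(rows, `[`, character(1), 2)
  num <- t(vapply(rows, function(tk) as.numeric(tk[3:44]), numeric(42)))
  if (anyNA(num)) stop("non-numeric PSSM entry in ", path)
  pssm <- num[, 1:20, drop = FALSE]
  pct <- num[, 21:40, drop = FALSE]
  ipp <- num[, 41]
  freqs <- matrix(0, n, 20, dimnames = list(NULL, PSSM_AA_ORDER))
  for (i in seq_len(n)) {
    s <- sum(pct[i, ])
    if (s > 0) freqs[i, ] <- pct[i, ] / s
    else freqs[i, match(query[i], PSSM_AA_ORDER)] <- 1
  }
  colnames(pssm) <- PSSM_AA_ORDER
  structure(list(length = n, query = query, freqs = freqs,
                 pssm = pssm, ipp = ipp),
            class = "sequence_profile")
}

#' Read a PSIPRED .ss2 secondary-structure prediction
#'
#' @param path .ss2 file (lines: index, residue, class, pC, pH, pE).
#' @return a \code{ss_prediction}: list with \code{length}, \code{aa},
#'   \code{prob} (n x 3 matrix, columns H/E/C, rows renormalized to sum 1)
#'   and \code{class} (argmax, one of "H","E","C").
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) stop("ss2 file not found: ", path)
  lines <- readLines(path)
  keep <- grepl("^\\s*[0-9]+\\s", lines)
  rows <- lines[keep]
  if (!length(rows)) stop("no prediction rows in ", path)
  prob <- matrix(0, length(rows), 3, dimnames = list(NULL, c("H", "E", "C")))
  aa <- character(length(rows))
  for (i in seq_along(rows)) {
    tk <- strsplit(trimws(rows[i]), "\\s+")[[1]]
    if (length(tk) != 6 || is.na(suppressWarnings(sum(as.numeric(tk[4:6])))))
      stop("ss2 format error at line ", which(keep)[i], " of ", path)
    aa[i] <- tk[2]
    p <- as.numeric(tk[4:6])   # file order: coil, helix, strand
    prob[i, ] <- c(p[2], p[3], p[1])
  }
  s <- rowSums(prob)
  if (any(s <= 0)) stop("zero probability row in ", path)
  prob <- prob / s
  structure(list(length = nrow(prob), aa = aa, prob = prob,
                 class = colnames(prob)[max.col(prob, ties.method = "first")]),
            class = "ss_prediction")
}

#' Read a two-class burial/exposure prediction
#'
#' Two-line format: the sequence, then a same-length string of \code{b}
#' (buried) / \code{e} (exposed).
#'
#' @param path prediction file.
#' @return an \code{exposure_prediction}: list with \code{length},
#'   \code{aa} and \code{class} (character vector of "b"/"e").
#' @export
read_exposure_prediction <- function(path) {
  if (!file.exists(path)) stop("exposure file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^>", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) stop("exposure file needs sequence + class lines: ", path)
  seq <- strsplit(trimws(lines[1]), "")[[1]]
  cls <- strsplit(trimws(lines[2]), "")[[1]]
  if (length(seq) != length(cls))
    stop("length mismatch between sequence (", length(seq),
         ") and classes (", length(cls), ") in ", path)
  if (!all(cls %in% c("b", "e")))
    stop("exposure classes must be 'b' or 'e' in ", path)
  structure(list(length = length(seq), aa = seq, class = cls),
            class = "exposure_prediction")
}

#' Read a single-record FASTA file
#'
#' @param path FASTA file.
#' @return one-letter character vector of the sequence.
#' @export
read_fasta_seq <- function(path) {
  fa <- bio3d::read.fasta(path)
  seq <- fa$ali[1, ]
  toupper(seq[seq != "-"])
}
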