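## Amino-acid alphabets, three-to-one letter mapping, and substitution scores.
## The BLOSUM62 matrix is taken from Biostrings' data, never re-typed here.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## Standard residues plus common modified residues mapped to their natural
## parent. Anything absent from this table becomes 'X'.
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
  ## modified residues with a close natural neighbour
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
  CME = "C", CSS = "C", OCS = "C", KCX = "K", MLY = "K",
  M3L = "K", HYP = "P", PCA = "Q", SEC = "C", PYL = "K",
  FME = "M", CSX = "C", LLP = "K", MLZ = "K", ALY = "K"
)

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

.aa_env <- new.env(parent = emptyenv())

#' BLOSUM62 substitution matrix
#'
#' Returns the BLOSUM62 amino-acid substitution matrix as shipped with
#' Biostrings. Used for consensus tie-breaking, reference scoring and the
#' built-in aligner.
#'
#' @return An integer matrix with amino-acid one-letter row/column names.
#' @export
blosum62 <- function() {
  if (is.null(.aa_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .aa_env$blosum62 <- e$BLOSUM62
  }
  .aa_env$blosum62
}

#' Gap score for consensus similarity scoring
#'
#' The score assigned to any position where either symbol is a gap (or the
#' unknown symbol 'X') when scoring a sequence against the MSA consensus.
#' Defined as one less than the minimum BLOSUM62 substitution score over the
#' 20 standard amino acids, i.e. strictly worse than the worst substitution.
#'
#' @return A single number (-5 with the standard BLOSUM62).
#' @export
gap_score <- function() {
  B <- blosum62()
  min(B[AA20, AA20]) - 1
}

## Map a three-letter residue name to the one-letter code; unmapped -> "X"
aa_three_to_one <- function(code) {
  out <- AA3TO1[toupper(code)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(code) {
  out <- AA1TO3[toupper(code)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
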