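## Sequence grouping: cluster chain sequences at configurable identity and
## coverage thresholds, align each cluster, and score alignment quality.
##
## The canonical backends are the external tools (MMseqs2 for clustering,
## MAFFT for alignment). A built-in greedy clusterer and a center-star
## progressive aligner are provided for test-scale data and for environments
## without the external tools; built-in alignments are flagged non-canonical.

## Uppercase a sequence and strip gap characters (for pairwise comparisons)
ungap <- function(s) gsub("-", "", s, fixed = TRUE)

## Pairwise identity and bidirectional coverage between two (unaligned)
## sequences, from an overlap alignment with BLOSUM62. Columns where either
## symbol is 'X' are excluded from both the match count and the aligned
## length, mirroring the gap-equivalence of 'X' elsewhere.
pair_identity_coverage <- function(s1, s2) {
  u1 <- toupper(ungap(s1)); u2 <- toupper(ungap(s2))
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(u1), Biostrings::AAString(u2),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "overlap")
  a1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- a1 != "-" & a2 != "-" & a1 != "X" & a2 != "X"
  A <- sum(both)
  M <- sum(both & a1 == a2)
  identity <- if (A == 0L) 0 else M / A
  cov1 <- A / nchar(u1)
  cov2 <- A / nchar(u2)
  list(identity = identity, coverage = c(cov1, cov2))
}

#' Cluster chain sequences by identity and coverage
#'
#' Groups sequences so that every member of a cluster shares at least
#' `identity` fractional sequence identity and bidirectional coverage of at
#' least `coverage` with the cluster representative. The built-in backend is
#' a greedy incremental clusterer (longest sequence first becomes a
#' representative; each following sequence joins the first representative it
#' matches), intended for test-scale data. The `"mmseqs2"` backend delegates
#' to the external tool and errors explicitly when it is unavailable.
#'
#' @param records list of `chain_record` objects (or a named character vector
#'   of sequences).
#' @param identity,coverage thresholds in (0, 1]; both default to 0.8.
#' @param backend `"builtin"` or `"mmseqs2"`.
#' @return A list of clusters, each a list with `member_ids` and
#'   `representative_id`.
#' @export
cluster_sequences <- function(records, identity = 0.8, coverage = 0.8,
                              backend = c("builtin", "mmseqs2")) {
  backend <- match.arg(backend)
  stopifnot_scalar_prob(identity, "identity")
  stopifnot_scalar_prob(coverage, "coverage")
  seqs <- records_to_seqs(records)
  if (backend == "mmseqs2") {
    if (Sys.which("mmseqs") == "")
      stop("the external clustering tool 'mmseqs' is not on PATH; ",
           "re-run with backend = \"builtin\"")
    return(cluster_sequences_mmseqs(seqs, identity, coverage))
  }
  ord <- order(-nchar(seqs), names(seqs))
  reps <- integer(0)
  assign <- integer(length(seqs))
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      pc <- pair_identity_coverage(seqs[[i]], seqs[[r]])
      if (pc$identity >= identity && min(pc$coverage) >= coverage) {
        assign[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  lapply(reps, function(r) {
    ids <- names(seqs)[assign == r]
    list(member_ids = sort(ids), representative_id = names(seqs)[r])
  })
}

cluster_sequences_mmseqs <- function(seqs, identity, coverage) {
  td <- tempfile("mmseqs")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  fa <- file.path(td, "in.fasta")
  write_fasta(names(seqs), toupper(seqs), fa)
  db <- file.path(td, "DB")
  system2("mmseqs", c("createdb", fa, db), stdout = FALSE, stderr = FALSE)
  ## command shape used upstream: cluster DB clusterDB tmp --cov-mode 0
  status <- system2("mmseqs", c("cluster", db, file.path(td, "clusterDB"),
                                file.path(td, "tmp"), "--cov-mode", "0",
                                "-c", coverage, "--min-seq-id", identity),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("mmseqs cluster failed")
  tsv <- file.path(td, "clusters.tsv")
  system2("mmseqs", c("createtsv", db, db, file.path(td, "clusterDB"), tsv),
          stdout = FALSE, stderr = FALSE)
  tab <- utils::read.table(tsv, sep = "\t", stringsAsFactors = FALSE)
  sp <- split(tab[[2]], tab[[1]])
  lapply(names(sp), function(r) list(member_ids = sort(unique(sp[[r]])),
                                     representative_id = r))
}

records_to_seqs <- function(records) {
  if (is.character(records)) {
    if (is.null(names(records))) names(records) <- sprintf("seq%03d", seq_along(records))
    return(records)
  }
  setNames(vapply(records, function(r) r$sequence, ""),
           vapply(records, function(r) r$id, ""))
}

## ---------------------------------------------------------------------------
## Alignment

#' Align the sequences of a cluster
#'
#' Aligns the given sequences and post-processes the alignment: columns
#' containing only 'X' or gaps are removed and rows are reordered
#' lexicographically by (structure code, chain). Case is preserved, so
#' lowercase (unresolved) letters survive the alignment.
#'
#' @param seqs named character vector of sequences (case-encoded).
#' @param backend `"auto"` (MAFFT when on PATH, else built-in), `"mafft"`, or
#'   `"builtin"` (center-star progressive alignment, BLOSUM62, affine gaps
#'   -11/-1; test-scale only).
#' @return A `protein_msa` object: list with `ids`, `seqs` (aligned strings),
#'   `n_cols`, and the backend used.
#' @export
align_cluster <- function(seqs, backend = c("auto", "mafft", "builtin")) {
  backend <- match.arg(backend)
  seqs <- records_to_seqs(seqs)
  stopifnot(length(seqs) >= 1L)
  if (backend == "auto")
    backend <- if (Sys.which("mafft") != "") "mafft" else "builtin"
  if (length(seqs) == 1L) {
    msa <- protein_msa(names(seqs), unname(seqs))
  } else if (backend == "mafft") {
    msa <- align_mafft(seqs)
  } else {
    msa <- align_center_star(seqs)
  }
  msa$backend <- backend
  postprocess_msa(msa)
}

align_mafft <- function(seqs) {
  fin <- tempfile(fileext = ".fasta")
  fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)))
  write_fasta(names(seqs), unname(seqs), fin)
  status <- system2("mafft", c("--auto", "--amino", "--preservecase", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0) stop("mafft failed with status ", status)
  fa <- read_fasta(fout)
  ## mafft preserves input order with --preservecase; map back by name
  protein_msa(fa$ids, fa$seqs)
}

## Center-star progressive alignment: choose the sequence with the highest
## summed pairwise alignment score as the center, align every other sequence
## to it, and merge the pairwise alignments on the center's coordinates.
align_center_star <- function(seqs) {
  up <- toupper(seqs)
  n <- length(seqs)
  score <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(up[[i]]), Biostrings::AAString(up[[j]]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    score[i, j] <- score[j, i] <- s
  }
  center <- which.max(rowSums(score))
  pats <- list()
  for (j in seq_len(n)) {
    if (j == center) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(up[[center]]), Biostrings::AAString(up[[j]]),
      substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
      type = "global")
    pats[[as.character(j)]] <- list(
      c = strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]],
      s = strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]])
  }
  ## Merged column plan: for each center residue, the max number of insertion
  ## columns preceding it across pairwise alignments (plus trailing ones).
  Lc <- nchar(seqs[[center]])
  ins_before <- integer(Lc + 1L)  # insertions before residue k (k = 1..Lc+1)
  per_seq_ins <- list()
  for (key in names(pats)) {
    cc <- pats[[key]]$c
    pos <- 0L
    runs <- integer(Lc + 1L)
    for (t in seq_along(cc)) {
      if (cc[t] == "-") runs[pos + 1L] <- runs[pos + 1L] + 1L else pos <- pos + 1L
    }
    per_seq_ins[[key]] <- runs
    ins_before <- pmax(ins_before, runs)
  }
  width <- Lc + sum(ins_before)
  rows <- matrix("-", n, width)
  ## columns for center residues: after the insertions preceding each
  ccols <- integer(Lc)
  cpos <- 0L
  for (k in seq_len(Lc)) {
    cpos <- cpos + ins_before[k] + 1L
    ccols[k] <- cpos
  }
  rows[center, ccols] <- strsplit(seqs[[center]], "")[[1]]
  for (key in names(pats)) {
    j <- as.integer(key)
    cc <- pats[[key]]$c
    ss_raw <- strsplit(seqs[[j]], "")[[1]]  # original case
    ss <- pats[[key]]$s
    ## walk the pairwise alignment, emitting into merged columns
    runs <- per_seq_ins[[key]]
    out <- rep("-", width)
    pos <- 0L     # center residue index consumed
    sused <- 0L   # subject residues consumed
    ins_used <- 0L
    for (t in seq_along(cc)) {
      if (cc[t] == "-") {
        ins_used <- ins_used + 1L
        target <- (if (pos == 0L) 0L else ccols[pos]) + ins_used
        if (ss[t] != "-") {
          sused <- sused + 1L
          out[target] <- ss_raw[sused]
        }
      } else {
        pos <- pos + 1L
        ins_used <- 0L
        if (ss[t] != "-") {
          sused <- sused + 1L
          out[ccols[pos]] <- ss_raw[sused]
        }
      }
    }
    rows[j, ] <- out
  }
  protein_msa(names(seqs), apply(rows, 1L, paste, collapse = ""))
}

#' Construct an MSA object
#'
#' @param ids row identifiers (chain ids).
#' @param seqs aligned strings of equal length.
#' @return A `protein_msa` object.
#' @export
protein_msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  w <- unique(nchar(seqs))
  if (length(w) > 1L) stop("aligned strings have unequal lengths")
  structure(list(ids = as.character(ids), seqs = as.character(seqs),
                 n_cols = if (length(w)) w else 0L),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("<protein_msa: %d sequences x %d columns>\n",
              length(x$ids), x$n_cols))
  invisible(x)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

## Column is "empty" if every row holds a gap or an 'X' (either case)
msa_empty_cols <- function(mat) {
  apply(mat, 2L, function(col) all(col == "-" | toupper(col) == "X"))
}

#' Post-process an alignment
#'
#' Removes columns consisting only of 'X' symbols or gaps and reorders the
#' rows lexicographically by identifier (PDB-style code, then chain).
#'
#' @param msa a `protein_msa`.
#' @return The post-processed `protein_msa`.
#' @export
postprocess_msa <- function(msa) {
  mat <- msa_matrix(msa)
  keep <- !msa_empty_cols(mat)
  mat <- mat[, keep, drop = FALSE]
  ord <- order(msa$ids)
  out <- protein_msa(msa$ids[ord],
                     apply(mat[ord, , drop = FALSE], 1L, paste, collapse = ""))
  out$backend <- msa$backend
  out
}

## ---------------------------------------------------------------------------
## MSA quality

#' MSA identity and coverage
#'
#' Identity is the average over columns of the percentage of row pairs
#' sharing the same amino acid in that column; pairs where either row holds a
#' gap (or 'X') are excluded from the column's denominator. Coverage is the
#' percentage of columns whose gap proportion is below 20%.
#'
#' @param msa a `protein_msa`.
#' @return Named numeric vector `c(identity, coverage)`, both in [0, 100].
#' @export
msa_identity_coverage <- function(msa) {
  mat <- toupper(msa_matrix(msa))
  n <- nrow(mat)
  if (n == 1L) {
    return(c(identity = 100, coverage = 100 * mean(colMeans(mat == "-" | mat == "X") < 0.2)))
  }
  col_ident <- apply(mat, 2L, function(col) {
    res <- col[col != "-" & col != "X"]
    k <- length(res)
    if (k < 2L) return(NA_real_)
    tab <- table(res)
    same <- sum(tab * (tab - 1) / 2)
    same / (k * (k - 1) / 2)
  })
  gapfrac <- apply(mat, 2L, function(col) mean(col == "-" | col == "X"))
  c(identity = 100 * mean(col_ident, na.rm = TRUE),
    coverage = 100 * mean(gapfrac < 0.2))
}

#' Normalised sum-of-pairs score of an MSA
#'
#' Raw score: over all columns and row pairs, +1 for a match, -0.5 for a
#' mismatch, -0.5 for a residue aligned to a gap; gap-gap pairs contribute 0
#' and 'X' counts as a gap. The raw score is divided by choose(n, 2) times
#' the effective length of the MSA (the maximum, over rows, of the number of
#' amino-acid characters), so that n identical ungapped rows score 1.
#'
#' @param msa a `protein_msa` with at least 2 rows.
#' @return A single number <= 1.
#' @export
sum_of_pairs_score <- function(msa) {
  mat <- toupper(msa_matrix(msa))
  n <- nrow(mat)
  stopifnot(n >= 2L)
  mat[mat == "X"] <- "-"
  raw <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mat[i, ]; b <- mat[j, ]
    both <- a != "-" & b != "-"
    raw <- raw + sum(both & a == b) - 0.5 * sum(both & a != b) -
      0.5 * sum(xor(a == "-", b == "-"))
  }
  l_eff <- max(rowSums(mat != "-"))
  raw / (choose(n, 2) * l_eff)
}
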