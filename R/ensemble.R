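## Conformational ensembles: a set of superimposed conformations over the
## columns of a cluster MSA, with per-position confidence weights and a
## resolved-mask. The reference conformation is the one whose sequence is
## most similar to the MSA consensus; superposition minimises the
## (optionally) weighted least-squares deviation to the reference.

#' Build a conformational ensemble from chain records and an MSA
#'
#' Maps each MSA row onto its chain record and assembles the n x 3m matrix of
#' Calpha coordinates per alignment column. Positions holding a gap, an 'X'
#' or a lowercase (unresolved) letter contribute no coordinates and are FALSE
#' in the resolved mask.
#'
#' @param records list of `chain_record`s; ids must cover the MSA rows.
#' @param msa a `protein_msa` over (a subset of) the records.
#' @param weighting use per-position coverage weights in superposition and
#'   decomposition?
#' @param centering `"mean"` or `"reference"`: conformation used to center
#'   the data (and to fill unresolved coordinates).
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(records, msa, weighting = TRUE,
                          centering = c("mean", "reference")) {
  centering <- match.arg(centering)
  ids <- vapply(records, function(r) r$id, "")
  names(records) <- ids
  if (!all(msa$ids %in% ids))
    stop("MSA rows without a matching chain record: ",
         paste(setdiff(msa$ids, ids), collapse = ", "))
  n <- length(msa$ids)
  m <- msa$n_cols
  R <- matrix(NA_real_, n, 3L * m)
  mask <- matrix(FALSE, n, m)
  col_map <- matrix(NA_integer_, n, m)
  members <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- records[[msa$ids[i]]]
    members[[i]] <- rec
    chars <- strsplit(msa$seqs[i], "")[[1]]
    ridx <- 0L
    for (j in seq_len(m)) {
      if (chars[j] == "-") next
      ridx <- ridx + 1L
      col_map[i, j] <- ridx
      if (chars[j] %in% AA20 && rec$residues$resolved[ridx]) {
        mask[i, j] <- TRUE
        R[i, (3L * j - 2L):(3L * j)] <-
          as.numeric(rec$residues[ridx, c("ca_x", "ca_y", "ca_z")])
      }
    }
    if (ridx != nrow(rec$residues))
      stop(sprintf("MSA row %s does not match its chain record length", rec$id))
  }
  structure(list(
    msa = msa, member_ids = msa$ids, members = members,
    R = R, resolved_mask = mask, col_map = col_map,
    n = n, m = m,
    weights = if (weighting) position_weights(msa) else rep(1, m),
    weighting = weighting, centering = centering,
    reference_index = NULL, superimposed = FALSE,
    dropped = character(0)
  ), class = "conf_ensemble")
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat(sprintf("<conf_ensemble: %d conformations x %d positions%s%s>\n",
              x$n, x$m,
              if (isTRUE(x$superimposed)) ", superimposed" else "",
              if (!is.null(x$reference_index))
                paste0(", reference ", x$member_ids[x$reference_index]) else ""))
  invisible(x)
}

#' @method summary conf_ensemble
#' @export
summary.conf_ensemble <- function(object, ...) {
  M <- rmsd_matrix(object)$values
  cat(sprintf("Conformational ensemble: n = %d, m = %d positions\n",
              object$n, object$m))
  if (!is.null(object$reference_index))
    cat("Reference:", object$member_ids[object$reference_index], "\n")
  cat(sprintf("Coverage weights: min %.2f, mean %.2f\n",
              min(object$weights), mean(object$weights)))
  cat(sprintf("Max pairwise RMSD: %.3f A\n", max(M, na.rm = TRUE)))
  invisible(object)
}

## ---------------------------------------------------------------------------
## Consensus and reference

#' Consensus sequence of an MSA
#'
#' Per column, the modal symbol among the 20 amino acids and the gap, 'X'
#' counting as a gap. Ties prefer an amino acid over a gap (favouring longer
#' references), then the amino acid with the higher BLOSUM62 self-score, then
#' the alphabetically smaller letter. `invert_priority` flips the first two
#' rules (gap over amino acid, lower self-score first), reproducing the
#' robustness experiment on the reference choice.
#'
#' @param msa a `protein_msa`.
#' @param invert_priority invert the tie-breaking rules?
#' @return List with `consensus` (character string over the 20 amino acids
#'   and '-') and `column_frequencies` (21 x P matrix, columns sum to 1).
#' @export
consensus_sequence <- function(msa, invert_priority = FALSE) {
  mat <- toupper(msa_matrix(msa))
  mat[mat == "X"] <- "-"
  symbols <- c(AA20, "-")
  B <- blosum62()
  self <- c(diag(B[AA20, AA20]), -Inf)  # gap ranked below every amino acid
  names(self) <- symbols
  freqs <- apply(mat, 2L, function(col) {
    tab <- table(factor(col, levels = symbols))
    as.numeric(tab) / length(col)
  })
  rownames(freqs) <- symbols
  pick <- function(f) {
    cand <- symbols[f == max(f)]
    if (length(cand) == 1L) return(cand)
    if (!invert_priority) {
      aa <- setdiff(cand, "-")
      if (length(aa) > 0L) cand <- aa
      best <- self[cand] == max(self[cand])
    } else {
      if ("-" %in% cand) return("-")
      best <- self[cand] == min(self[cand])
    }
    sort(cand[best])[1]
  }
  cons <- apply(freqs, 2L, pick)
  list(consensus = paste(cons, collapse = ""), column_frequencies = freqs)
}

#' Score an aligned sequence against the consensus
#'
#' Sum over positions of the BLOSUM62 substitution score between the
#' sequence symbol and the consensus symbol; any position where either
#' symbol is a gap or 'X' contributes the gap score (min BLOSUM62 - 1 = -5).
#' Lowercase (unresolved) letters score as their amino acid.
#'
#' @param aligned_seq aligned sequence string (length P).
#' @param consensus consensus string (length P).
#' @return The integer score.
#' @export
score_against_consensus <- function(aligned_seq, consensus) {
  s <- toupper(strsplit(aligned_seq, "")[[1]])
  cs <- toupper(strsplit(consensus, "")[[1]])
  if (length(s) != length(cs))
    stop("sequence and consensus have different lengths")
  B <- blosum62()
  g <- gap_score()
  total <- 0
  for (i in seq_along(s)) {
    if (s[i] %in% c("-", "X") || cs[i] %in% c("-", "X")) total <- total + g
    else total <- total + B[s[i], cs[i]]
  }
  total
}

#' Select the reference conformation of an MSA
#'
#' The row whose sequence scores highest against the consensus
#' ([score_against_consensus()]); ties resolved by the lexicographically
#' smallest identifier. Deterministic.
#'
#' @inheritParams consensus_sequence
#' @return The selected row index.
#' @export
select_reference <- function(msa, invert_priority = FALSE) {
  cons <- consensus_sequence(msa, invert_priority)$consensus
  scores <- vapply(msa$seqs, score_against_consensus, 0, consensus = cons)
  order(-scores, msa$ids)[1]
}

#' Per-position coverage weights
#'
#' The confidence weight of alignment column i is the fraction of rows with
#' a resolved residue (uppercase amino-acid letter) at that column.
#'
#' @param msa a `protein_msa`.
#' @return Numeric vector of length `n_cols`, in (0, 1].
#' @export
position_weights <- function(msa) {
  mat <- msa_matrix(msa)
  resolved <- matrix(mat %in% AA20, nrow(mat), ncol(mat))
  colMeans(resolved)
}

## ---------------------------------------------------------------------------
## Weighted superposition

#' Weighted least-squares superposition of paired coordinates
#'
#' Finds the proper rotation and translation minimising
#' sum_i w_i || (x_i - tx) Q - (y_i - ty) ||^2 for paired coordinate rows,
#' via SVD of the weighted cross-covariance with reflection correction
#' (weighted Kabsch). With equal weights this is the classical
#' least-squares fit.
#'
#' @param X,Y k x 3 matrices of paired coordinates (mobile, target).
#' @param w length-k non-negative weights (default all 1).
#' @return List with rotation `Q` (3 x 3, applied on the right of centred
#'   rows), weighted centroids `tx`, `ty`, the fitted coordinates `Xfit`,
#'   weighted `rmsd`, and `degenerate` (TRUE when the weighted
#'   cross-covariance is rank-deficient, e.g. collinear points).
#' @export
superpose_fit <- function(X, Y, w = NULL) {
  stopifnot(nrow(X) == nrow(Y), ncol(X) == 3L, ncol(Y) == 3L)
  k <- nrow(X)
  if (is.null(w)) w <- rep(1, k)
  stopifnot(length(w) == k, all(w >= 0), sum(w) > 0)
  wn <- w / sum(w)
  tx <- colSums(X * wn)
  ty <- colSums(Y * wn)
  Xc <- sweep(X, 2L, tx)
  Yc <- sweep(Y, 2L, ty)
  H <- t(Xc) %*% (Yc * wn)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  S <- diag(c(1, 1, d))
  Q <- sv$u %*% S %*% t(sv$v)
  Xfit <- sweep(Xc %*% Q, 2L, ty, `+`)
  rmsd <- sqrt(sum(wn * rowSums((Xfit - Y)^2)))
  list(Q = Q, tx = tx, ty = ty, Xfit = Xfit, rmsd = rmsd,
       degenerate = sv$d[2] < 1e-10 * max(sv$d[1], 1))
}

ens_row_xyz <- function(ens, i) unflatten_xyz(ens$R[i, ])

apply_transform_record <- function(rec, tx, Q, ty) {
  res <- rec$residues
  for (cols in list(c("n_x", "n_y", "n_z"), c("ca_x", "ca_y", "ca_z"),
                    c("c_x", "c_y", "c_z"), c("o_x", "o_y", "o_z"))) {
    xyz <- as.matrix(res[, cols])
    ok <- stats::complete.cases(xyz)
    if (any(ok))
      res[ok, cols] <- sweep(sweep(xyz[ok, , drop = FALSE], 2L, tx) %*% Q,
                             2L, ty, `+`)
  }
  rec$residues <- res
  rec
}

#' Superimpose all conformations onto the reference
#'
#' Translates every conformation so that its weighted centroid (over the
#' positions shared with the reference) is at the reference frame origin and
#' rotates it by the proper rotation minimising the weighted least-squares
#' deviation to the reference. Conformations sharing fewer than
#' `min_aligned` resolved positions with the reference are dropped and
#' reported in `$dropped`.
#'
#' @param ensemble a `conf_ensemble` with a selected reference (set with
#'   [select_reference()]; selected automatically if absent).
#' @param atoms `"ca"` to fit on Calpha atoms only, `"backbone"` to fit on
#'   N/CA/C/O (each atom carrying its position's weight).
#' @param min_aligned minimum shared resolved positions (default 5).
#' @return The superimposed `conf_ensemble`.
#' @export
superimpose_ensemble <- function(ensemble, atoms = c("ca", "backbone"),
                                 min_aligned = 5L) {
  atoms <- match.arg(atoms)
  ens <- ensemble
  if (is.null(ens$reference_index))
    ens$reference_index <- select_reference(ens$msa)
  ref <- ens$reference_index
  w <- ens$weights
  ## center the reference at its own weighted centroid
  rmask <- ens$resolved_mask[ref, ]
  Yall <- ens_row_xyz(ens, ref)
  wr <- w[rmask] / sum(w[rmask])
  ref_centroid <- colSums(Yall[rmask, , drop = FALSE] * wr)
  I3 <- diag(3)
  ens$R[ref, ] <- flatten_xyz(sweep(Yall, 2L, ref_centroid))
  ens$members[[ref]] <- apply_transform_record(ens$members[[ref]],
                                               ref_centroid, I3, c(0, 0, 0))
  keep <- rep(TRUE, ens$n)
  degenerate <- logical(ens$n)
  for (i in seq_len(ens$n)) {
    if (i == ref) next
    shared <- ens$resolved_mask[i, ] & ens$resolved_mask[ref, ]
    if (sum(shared) < min_aligned) { keep[i] <- FALSE; next }
    if (atoms == "ca") {
      X <- ens_row_xyz(ens, i)[shared, , drop = FALSE]
      Y <- ens_row_xyz(ens, ref)[shared, , drop = FALSE]
      ws <- w[shared]
    } else {
      bb <- backbone_pair(ens, i, ref, shared)
      X <- bb$X; Y <- bb$Y; ws <- bb$w
    }
    fit <- superpose_fit(X, Y, ws)
    degenerate[i] <- fit$degenerate
    Xi <- ens_row_xyz(ens, i)
    ens$R[i, ] <- flatten_xyz(sweep(Xi, 2L, fit$tx) %*% fit$Q)
    ens$members[[i]] <- apply_transform_record(ens$members[[i]], fit$tx,
                                               fit$Q, c(0, 0, 0))
  }
  dropped <- ens$member_ids[!keep]
  if (any(!keep)) ens <- ens_subset(ens, which(keep))
  ens$dropped <- c(ensemble$dropped, dropped)
  ens$degenerate_fits <- ens$member_ids[degenerate[keep]]
  ens$superimposed <- TRUE
  ens$atoms <- atoms
  ens
}

backbone_pair <- function(ens, i, ref, shared) {
  cols <- c("n_x", "n_y", "n_z", "ca_x", "ca_y", "ca_z",
            "c_x", "c_y", "c_z", "o_x", "o_y", "o_z")
  ri <- ens$members[[i]]$residues[ens$col_map[i, shared], cols]
  rr <- ens$members[[ref]]$residues[ens$col_map[ref, shared], cols]
  Xi <- matrix(as.numeric(as.matrix(ri)), ncol = 3L, byrow = TRUE)
  Yr <- matrix(as.numeric(as.matrix(rr)), ncol = 3L, byrow = TRUE)
  w4 <- rep(ens$weights[shared], each = 4L)
  ok <- stats::complete.cases(Xi) & stats::complete.cases(Yr)
  list(X = Xi[ok, , drop = FALSE], Y = Yr[ok, , drop = FALSE], w = w4[ok])
}

ens_subset <- function(ens, idx) {
  ref_id <- if (!is.null(ens$reference_index))
    ens$member_ids[ens$reference_index] else NULL
  out <- ens
  out$msa <- protein_msa(ens$msa$ids[idx], ens$msa$seqs[idx])
  out$member_ids <- ens$member_ids[idx]
  out$members <- ens$members[idx]
  out$R <- ens$R[idx, , drop = FALSE]
  out$resolved_mask <- ens$resolved_mask[idx, , drop = FALSE]
  out$col_map <- ens$col_map[idx, , drop = FALSE]
  out$n <- length(idx)
  if (!is.null(ref_id)) out$reference_index <- match(ref_id, out$member_ids)
  out
}

## ---------------------------------------------------------------------------
## Redundancy reduction and RMSD

pair_rmsd <- function(ens, i, j) {
  shared <- ens$resolved_mask[i, ] & ens$resolved_mask[j, ]
  if (!any(shared)) return(NA_real_)
  di <- ens_row_xyz(ens, i)[shared, , drop = FALSE] -
    ens_row_xyz(ens, j)[shared, , drop = FALSE]
  sqrt(mean(rowSums(di^2)))
}

## Is sequence A included in sequence B? At every column, A's symbol is a gap
## or equals B's symbol (case-insensitive), and every resolved position of A
## is resolved in B.
sequence_included <- function(ens, a, b) {
  sa <- toupper(strsplit(ens$msa$seqs[a], "")[[1]])
  sb <- toupper(strsplit(ens$msa$seqs[b], "")[[1]])
  if (!all(sa == "-" | sa == sb)) return(FALSE)
  all(ens$resolved_mask[b, ens$resolved_mask[a, ]])
}

#' Remove structurally redundant conformations
#'
#' Drops any conformation A deviating by less than `rms_cut` (Calpha RMSD
#' over shared positions, in the common frame) from a retained conformation
#' B whose sequence contains A's. Conformations are visited in a
#' deterministic keep-first order (resolved length descending, then id
#' ascending); the reference conformation is always retained.
#'
#' @param ensemble a superimposed `conf_ensemble`.
#' @param rms_cut RMSD threshold in Angstrom (default 0.1).
#' @return The reduced `conf_ensemble`; removed ids in `$removed_redundant`.
#' @export
reduce_redundancy <- function(ensemble, rms_cut = 0.1) {
  ens <- ensemble
  if (ens$n <= 1L) return(ens)
  len <- rowSums(ens$resolved_mask)
  ord <- order(-len, ens$member_ids)
  ref <- ens$reference_index
  if (!is.null(ref)) ord <- c(ref, setdiff(ord, ref))
  kept <- integer(0)
  removed <- integer(0)
  for (i in ord) {
    dup <- FALSE
    for (b in kept) {
      r <- pair_rmsd(ens, i, b)
      if (!is.na(r) && r < rms_cut && sequence_included(ens, i, b)) {
        dup <- TRUE
        break
      }
    }
    if (dup) removed <- c(removed, i) else kept <- c(kept, i)
  }
  out <- ens_subset(ens, sort(kept))
  out$removed_redundant <- ens$member_ids[sort(removed)]
  out
}

#' All-to-all pairwise RMSD matrix
#'
#' Calpha RMSD over the positions resolved in both members of each pair,
#' computed in the common superposition frame. Pairs with no shared resolved
#' position are reported as NA.
#'
#' @param ensemble a (superimposed) `conf_ensemble`.
#' @return List with `values`: a symmetric n x n matrix with zero diagonal.
#' @export
rmsd_matrix <- function(ensemble) {
  n <- ensemble$n
  M <- matrix(0, n, n, dimnames = list(ensemble$member_ids, ensemble$member_ids))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      M[i, j] <- M[j, i] <- pair_rmsd(ensemble, i, j)
  structure(list(values = M), class = "rmsd_matrix")
}

## ---------------------------------------------------------------------------
## Missing data

#' Fill unresolved coordinates with the centering conformation
#'
#' Unresolved entries of the coordinate matrix are replaced by the
#' coordinates of the conformation used to center the data: the per-column
#' mean over resolved rows (default) or the reference conformation (its own
#' unresolved positions completed by the column means). Resolved entries are
#' untouched. Filling with the centering conformation avoids reconstruction
#' bias and shrinks the variance of poorly covered columns.
#'
#' @param ensemble a superimposed `conf_ensemble`.
#' @param centering `"mean"` or `"reference"`; defaults to the ensemble's
#'   configured centering.
#' @return The ensemble with `$R_dense` (gap-filled n x 3m matrix) and
#'   `$center` (the 3m centering conformation).
#' @export
fill_gaps <- function(ensemble, centering = NULL) {
  ens <- ensemble
  centering <- centering %||% ens$centering
  ## expand mask to 3m: column j of mask covers R columns 3j-2..3j
  mask3 <- ens$resolved_mask[, rep(seq_len(ens$m), each = 3L), drop = FALSE]
  col_mean <- numeric(3L * ens$m)
  for (jj in seq_len(3L * ens$m)) {
    v <- ens$R[mask3[, jj], jj]
    col_mean[jj] <- if (length(v)) mean(v) else NA_real_
  }
  if (anyNA(col_mean))
    stop("alignment column with no resolved residue; post-process the MSA first")
  if (centering == "reference") {
    if (is.null(ens$reference_index)) stop("no reference selected")
    center <- ens$R[ens$reference_index, ]
    center[is.na(center)] <- col_mean[is.na(center)]
  } else {
    center <- col_mean
  }
  Rd <- ens$R
  for (jj in seq_len(3L * ens$m)) Rd[!mask3[, jj], jj] <- center[jj]
  ens$R_dense <- Rd
  ens$center <- center
  ens$centering <- centering
  ens
}

#' Build, superimpose and prune an ensemble in one call
#'
#' Convenience wrapper: constructs the ensemble, selects the reference,
#' superimposes, reduces redundancy and fills gaps.
#'
#' @inheritParams conf_ensemble
#' @inheritParams superimpose_ensemble
#' @inheritParams reduce_redundancy
#' @param reference_id optional member id to force as reference.
#' @return A superimposed, pruned, gap-filled `conf_ensemble`.
#' @export
build_ensemble <- function(records, msa, weighting = TRUE,
                           centering = c("mean", "reference"),
                           atoms = "ca", min_aligned = 5L, rms_cut = 0.1,
                           reference_id = NULL) {
  centering <- match.arg(centering)
  ens <- conf_ensemble(records, msa, weighting = weighting,
                       centering = centering)
  ens$reference_index <- if (is.null(reference_id)) select_reference(msa)
  else match(reference_id, ens$member_ids)
  if (is.na(ens$reference_index)) stop("reference_id not among members")
  ens <- superimpose_ensemble(ens, atoms = atoms, min_aligned = min_aligned)
  ens <- reduce_redundancy(ens, rms_cut = rms_cut)
  fill_gaps(ens)
}
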