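test_that("consensus prefers amino acids, then higher BLOSUM62 self-score", {
  expect_equal(consensus_sequence(msa_of("A", "A", "-"))$consensus, "A")
  expect_equal(consensus_sequence(msa_of("A", "-"))$consensus, "A")
  ## L vs W tie: sigma(W,W) = 11 > sigma(L,L) = 4
  B <- blosum62()
  expect_gt(B["W", "W"], B["L", "L"])
  expect_equal(consensus_sequence(msa_of("L", "W"))$consensus, "W")
  ## X counts as gap
  expect_equal(consensus_sequence(msa_of("X", "X", "C"))$consensus, "-")
  ## frequencies sum to 1 per column
  fr <- consensus_sequence(msa_of("AC", "A-", "GC"))$column_frequencies
  expect_equal(colSums(fr), rep(1, 2), ignore_attr = TRUE)
  ## inverted priority rules flip both tie-breaks
  expect_equal(consensus_sequence(msa_of("A", "-"),
                                  invert_priority = TRUE)$consensus, "-")
  expect_equal(consensus_sequence(msa_of("L", "W"),
                                  invert_priority = TRUE)$consensus, "L")
})

test_that("consensus scoring uses BLOSUM62 with gap score -5", {
  expect_equal(score_against_consensus("AAAA", "AAAA"), 16)
  expect_equal(score_against_consensus("A-", "AA"), -1)
  expect_equal(score_against_consensus("--", "AA"), -10)
  ## lowercase (unresolved) residues score as their amino acid
  expect_equal(score_against_consensus("aaaa", "AAAA"), 16)
  expect_error(score_against_consensus("AAA", "AAAA"), "length")
})

test_that("reference selection maximises the consensus score deterministically", {
  ## a row equal to the consensus wins
  msa <- msa_of("ACDEF", "ACDEF", "ACDEW")
  expect_equal(select_reference(msa), 1L)
  ## equal scores: lexicographically smallest id
  tie <- protein_msa(c("B000_A", "A000_A"), c("ACDEF", "ACDEF"))
  expect_equal(tie$ids[select_reference(tie)], "A000_A")
  ## a heavily gapped row never beats an ungapped row with equal residues
  gap <- msa_of("ACDEFGHIKL", "ACDEF-----", "ACDEFGHIKL")
  scores <- vapply(gap$seqs, score_against_consensus, 0,
                   consensus = consensus_sequence(gap)$consensus)
  expect_equal(unname(which.max(scores)), select_reference(gap))
  expect_false(select_reference(gap) == 2L)
})

test_that("position weights equal the column coverage", {
  msa <- msa_of("ACDE", "ACDE", "AC-E", "ACD-")
  expect_equal(position_weights(msa), c(1, 1, 0.75, 0.75))
  ## lowercase and X are not resolved
  msa2 <- msa_of("Ax", "AX", "Aa", "AA")
  expect_equal(position_weights(msa2), c(1, 0.25))
})

test_that("weighted superposition recovers exact rigid transforms", {
  set.seed(5)
  Y <- matrix(rnorm(30), 10, 3)
  ## identity case
  f0 <- superpose_fit(Y, Y)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$Q, diag(3), tolerance = 1e-8)
  ## known rotation + translation recovered
  Rot <- random_rotation()
  X <- sweep(Y %*% Rot, 2, c(3, -2, 7), `+`)
  f1 <- superpose_fit(X, Y, w = runif(10, 0.2, 1))
  expect_lt(f1$rmsd, 1e-8)
  expect_equal(f1$Xfit, Y, tolerance = 1e-8)
})

test_that("zero-weight positions are excluded exactly from the fit", {
  set.seed(6)
  Y <- matrix(rnorm(24), 8, 3)
  X <- sweep(Y %*% random_rotation(), 2, c(1, 2, 3), `+`)
  X[8, ] <- X[8, ] + c(50, 0, 0)        # outlier position
  w <- c(rep(1, 7), 0)
  fw <- superpose_fit(X, Y, w)
  oracle <- oracle_kabsch(X[1:7, ], Y[1:7, ])
  expect_equal(fw$Xfit[1:7, ], oracle$Xfit, tolerance = 1e-8)
})

test_that("the fitted rotation minimises the weighted objective (Monte Carlo)", {
  set.seed(7)
  X <- matrix(rnorm(18), 6, 3)
  Y <- matrix(rnorm(18), 6, 3)
  w <- runif(6)
  obj <- function(Q) {
    wn <- w / sum(w)
    Xc <- sweep(X, 2, colSums(X * wn))
    Yc <- sweep(Y, 2, colSums(Y * wn))
    sum(wn * rowSums((Xc %*% Q - Yc)^2))
  }
  fit <- superpose_fit(X, Y, w)
  best <- obj(fit$Q)
  for (k in 1:300) expect_gte(obj(random_rotation()), best - 1e-10)
})

test_that("superposition of an ensemble is exact and idempotent", {
  fx <- make_linear_motion_ensemble(m = 15, n = 6, amplitude = 1, seed = 13)
  ens <- fx$ensemble
  ## scramble every conformation by a random rigid transform, then refit
  set.seed(99)
  scr <- ens
  for (i in seq_len(scr$n)) {
    Rot <- random_rotation()
    Xi <- confmotion:::unflatten_xyz(scr$R[i, ])
    scr$R[i, ] <- confmotion:::flatten_xyz(sweep(Xi %*% Rot, 2, rnorm(3, sd = 10), `+`))
  }
  fit1 <- superimpose_ensemble(scr)
  M1 <- rmsd_matrix(fit1)$values
  M0 <- rmsd_matrix(superimpose_ensemble(ens))$values
  expect_equal(M1, M0, tolerance = 1e-6)
  ## idempotence: refitting the fitted ensemble changes nothing
  fit2 <- superimpose_ensemble(fit1)
  expect_equal(fit2$R, fit1$R, tolerance = 1e-8)
})

test_that("conformations sharing too few positions with the reference are dropped", {
  fx <- make_linear_motion_ensemble(m = 12, n = 5, amplitude = 1, seed = 17)
  ens <- fx$ensemble
  ens$reference_index <- 1L
  ## member 3 shares only 4 resolved positions with the reference
  ens$resolved_mask[3, 5:12] <- FALSE
  out <- superimpose_ensemble(ens, min_aligned = 5)
  expect_equal(out$n, 4L)
  expect_equal(out$dropped, fx$ensemble$member_ids[3])
})

test_that("redundancy reduction honours RMSD cut, sequence inclusion and the reference", {
  fx <- make_linear_motion_ensemble(m = 12, n = 5, amplitude = 2, seed = 23)
  ens <- fx$ensemble
  ## append an exact duplicate of member 2 under a new id
  dup <- ens$members[[2]]
  dup$structure_id <- "SDUP"; dup$id <- "SDUP_A"
  recs <- c(ens$members, list(dup))
  msa <- protein_msa(c(ens$msa$ids, "SDUP_A"), c(ens$msa$seqs, ens$msa$seqs[2]))
  ens2 <- conf_ensemble(recs, msa, weighting = FALSE)
  ens2$reference_index <- select_reference(msa)
  ens2$superimposed <- TRUE
  red <- reduce_redundancy(ens2, rms_cut = 0.1)
  expect_equal(red$n, 5L)
  expect_equal(red$removed_redundant, "SDUP_A")
  ## the reference is never removed, even when redundant
  ens3 <- ens2
  ens3$reference_index <- match("SDUP_A", ens3$member_ids)
  red3 <- reduce_redundancy(ens3, rms_cut = 0.1)
  expect_true("SDUP_A" %in% red3$member_ids)
  expect_lte(red3$n, ens3$n)
})

test_that("close conformations with disjoint sequences are both kept", {
  ## two 6-residue chains, nearly identical coordinates, different residues
  ca <- confmotion:::random_ca_trace(6, seed = 31)
  r1 <- confmotion:::record_from_ca("S001", "A", ca, "ACDEFG")
  r2 <- confmotion:::record_from_ca("S002", "A", ca + 0.01, "KLMNPQ")
  msa <- protein_msa(c("S001_A", "S002_A"), c("ACDEFG", "KLMNPQ"))
  ens <- conf_ensemble(list(r1, r2), msa, weighting = FALSE)
  ens$reference_index <- 1L
  ens$superimposed <- TRUE
  red <- reduce_redundancy(ens, rms_cut = 0.1)
  expect_equal(red$n, 2L)
})

test_that("a truncated copy at RMSD 0 is removed as included", {
  ca <- confmotion:::random_ca_trace(10, seed = 37)
  full <- confmotion:::record_from_ca("S001", "A", ca, "ACDEFGHIKL")
  trunc <- confmotion:::record_from_ca("S002", "A", ca[1:7, ], "ACDEFGH")
  msa <- protein_msa(c("S001_A", "S002_A"), c("ACDEFGHIKL", "ACDEFGH---"))
  ens <- conf_ensemble(list(full, trunc), msa, weighting = FALSE)
  ens$reference_index <- 1L
  ens$superimposed <- TRUE
  red <- reduce_redundancy(ens, rms_cut = 0.1)
  expect_equal(red$member_ids, "S001_A")
  expect_equal(red$removed_redundant, "S002_A")
})

test_that("the RMSD matrix equals a brute-force recomputation", {
  fx <- make_linear_motion_ensemble(m = 10, n = 5, amplitude = 2,
                                    noise_sd = 0.1, seed = 41,
                                    missing_fraction = 0.15)
  ens <- fx$ensemble
  M <- rmsd_matrix(ens)$values
  expect_equal(unname(M), unname(t(M)))
  expect_equal(diag(M), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5) {
    sh <- ens$resolved_mask[i, ] & ens$resolved_mask[j, ]
    di <- confmotion:::unflatten_xyz(ens$R[i, ])[sh, , drop = FALSE] -
      confmotion:::unflatten_xyz(ens$R[j, ])[sh, , drop = FALSE]
    expect_equal(M[i, j], sqrt(mean(rowSums(di^2))), tolerance = 1e-10)
  }
  ## n = 1
  one <- rmsd_matrix(confmotion:::ens_subset(ens, 1L))$values
  expect_equal(one, matrix(0, 1, 1, dimnames = list(ens$member_ids[1],
                                                    ens$member_ids[1])))
})

test_that("gap filling uses the centering conformation and shrinks variance", {
  fx <- make_linear_motion_ensemble(m = 10, n = 6, amplitude = 2, seed = 43)
  ens <- fx$ensemble
  ## fully resolved: R_dense equals R
  expect_equal(fill_gaps(ens)$R_dense, ens$R)
  ## a column resolved in k of n rows: filled variance is (k-1)/(n-1) of the
  ## resolved sample variance
  ens$resolved_mask[1:3, 4] <- FALSE
  jj <- 3 * 3 + 1  # x coordinate of column 4
  resolved_vals <- ens$R[4:6, jj]
  ens2 <- fill_gaps(ens)
  filled <- ens2$R_dense[, jj]
  expect_equal(filled[1:3], rep(mean(resolved_vals), 3))
  expect_equal(stats::var(filled),
               stats::var(resolved_vals) * (3 - 1) / (6 - 1), tolerance = 1e-12)
  ## reference centering fills with the reference's coordinates
  ens$centering <- "reference"
  ens$reference_index <- 5L
  ens3 <- fill_gaps(ens)
  expect_equal(ens3$R_dense[1, jj], ens$R[5, jj])
})
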