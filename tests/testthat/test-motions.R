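test_that("SVD decomposition matches the explicit covariance eigensolver", {
  set.seed(3)
  R <- random_R(5, 4)  # 5 x 12
  dec <- motion_pca(R)
  C <- stats::cov(R)
  eg <- eigen(C, symmetric = TRUE)
  k <- length(dec$eigenvalues)
  expect_equal(dec$eigenvalues, eg$values[seq_len(k)], tolerance = 1e-8)
  for (j in seq_len(k))
    expect_equal(abs(sum(dec$modes[, j] * eg$vectors[, j])), 1,
                 tolerance = 1e-8)
  ## total variance identity
  rbar <- colMeans(R)
  expect_equal(dec$total_variance,
               sum(sweep(R, 2, rbar)^2) / (nrow(R) - 1), tolerance = 1e-10)
  ## modes orthonormal
  expect_equal(crossprod(dec$modes), diag(k), tolerance = 1e-8)
  ## projections of training data reproduce the eigenvalues
  expect_equal(apply(dec$scores, 2, stats::var), dec$eigenvalues,
               tolerance = 1e-8)
})

test_that("rank and duplication behave as the covariance predicts", {
  set.seed(4)
  R <- random_R(2, 5)
  expect_length(motion_pca(R)$eigenvalues, 1L)  # n=2, mean-centered: rank 1
  expect_error(motion_pca(R[1, , drop = FALSE]), "no variance")
  ## duplicating every conformation: same modes, eigenvalues follow the
  ## explicit covariance of the duplicated data
  R6 <- random_R(6, 5)
  dup <- rbind(R6, R6)
  d1 <- motion_pca(R6)
  d2 <- motion_pca(dup)
  eg <- eigen(stats::cov(dup), symmetric = TRUE)
  expect_equal(d2$eigenvalues, eg$values[seq_along(d2$eigenvalues)],
               tolerance = 1e-8)
  expect_equal(abs(sum(d1$modes[, 1] * d2$modes[, 1])), 1, tolerance = 1e-8)
  expect_equal(d2$eigenvalues[1] / d1$eigenvalues[1],
               2 * (6 - 1) / (12 - 1), tolerance = 1e-8)
})

test_that("dimensionality is the smallest K reaching the threshold", {
  dec <- list(eigenvalues = c(9, 1), total_variance = 10)
  class(dec) <- "motion_pca"
  expect_equal(dimensionality(dec, 90), 1L)
  expect_equal(dimensionality(dec, 95), 2L)
  expect_equal(dimensionality(dec, 50), 1L)
  ## isotropic noise: K grows toward the rank bound
  set.seed(8)
  iso <- motion_pca(random_R(12, 10))
  expect_gt(dimensionality(iso, 90), 7L)
  expect_lte(dimensionality(iso, 90), 11L)
})

test_that("collectivity hits its boundary values and the entropy formula", {
  m <- 10
  uniform <- rep(1 / sqrt(3 * m), 3 * m)
  expect_equal(collectivity(uniform, m), 1, tolerance = 1e-12)
  single <- c(1, rep(0, 3 * m - 1))
  expect_equal(collectivity(single, m), 1 / m, tolerance = 1e-12)
  ## m = 2 with per-atom weights (0.9, 0.1): direct entropy evaluation
  v <- c(sqrt(0.9), 0, 0, sqrt(0.1), 0, 0)
  oracle <- 0.5 * exp(-(0.9 * log(0.9) + 0.1 * log(0.1)))
  expect_equal(collectivity(v, 2), oracle, tolerance = 1e-12)
  expect_error(collectivity(rep(0, 6), 2), "zero")
})

test_that("RMSIP matches the brute-force double sum and bio3d", {
  set.seed(9)
  Q <- qr.Q(qr(matrix(rnorm(30 * 8), 30, 8)))
  A <- Q[, 1:4]; B <- Q[, 5:8]
  expect_equal(rmsip(A, A, 4), 1, tolerance = 1e-12)
  expect_equal(rmsip(A, B, 4), 0, tolerance = 1e-12)
  ## two random orthonormal subspaces vs explicit double loop
  QA <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  QB <- qr.Q(qr(matrix(rnorm(30 * 4), 30, 4)))
  acc <- 0
  for (i in 1:4) for (j in 1:4) acc <- acc + sum(QA[, i] * QB[, j])^2
  expect_equal(rmsip(QA, QB, 4), sqrt(acc / 4), tolerance = 1e-10)
  expect_equal(rmsip(QA, QB, 4), bio3d::rmsip(QA, QB, 4, 4)$rmsip,
               tolerance = 1e-8)
  expect_error(rmsip(QA, QB[1:27, ], 4), "coordinate spaces")
})

test_that("projection and generation are exact linear inverses", {
  fx <- make_linear_motion_ensemble(m = 12, n = 8, amplitude = 2, seed = 15)
  dec <- motion_pca(fx$ensemble)
  ctr_raw <- dec$center / confmotion:::rep3(dec$weights)
  ## r = center -> zero projection
  expect_equal(project_conformation(dec, ctr_raw), rep(0, length(dec$eigenvalues)),
               tolerance = 1e-8)
  ## r = center + 2 v1 -> (2, 0, ...)
  r2 <- dec$center + 2 * dec$modes[, 1]
  p2 <- project_conformation(dec, r2 / confmotion:::rep3(dec$weights))
  expect_equal(p2[1], 2, tolerance = 1e-8)
  if (length(p2) > 1) expect_equal(p2[-1], rep(0, length(p2) - 1),
                                   tolerance = 1e-8)
  ## project . generate = identity on amplitudes; generate . project = identity
  ## on conformations in the training span
  p <- rnorm(length(dec$eigenvalues))
  expect_equal(project_conformation(dec, generate_conformation(dec, p)), p,
               tolerance = 1e-8)
  r <- fx$ensemble$R_dense[3, ]
  expect_equal(generate_conformation(dec, project_conformation(dec, r)), r,
               tolerance = 1e-8)
  ## p = 0 returns the centering conformation (in Angstrom space)
  expect_equal(generate_conformation(dec, rep(0, length(p))), ctr_raw,
               tolerance = 1e-10)
  ## an unsuperimposed conformation triggers the frame warning
  expect_warning(project_conformation(dec, r + 100), "centroid")
})

test_that("uniform weights reproduce the unweighted decomposition exactly", {
  set.seed(10)
  R <- random_R(7, 6)
  d0 <- motion_pca(R)
  d1 <- motion_pca(R, weights = rep(1, 6))
  expect_equal(d0$eigenvalues, d1$eigenvalues, tolerance = 1e-12)
  expect_equal(d0$modes, d1$modes, tolerance = 1e-12)
})

test_that("weighting shrinks low-coverage positions and de-weights on output", {
  fx <- make_linear_motion_ensemble(m = 12, n = 10, amplitude = 2,
                                    missing_fraction = 0.3, seed = 19)
  ens <- fx$ensemble
  expect_true(ens$weighting)
  dec <- motion_pca(ens)
  expect_true(dec$weights_applied)
  ## generated conformations live in Angstrom space: p = 0 equals the
  ## de-weighted center
  g0 <- generate_conformation(dec, rep(0, length(dec$eigenvalues)))
  expect_equal(g0, dec$center / confmotion:::rep3(dec$weights),
               tolerance = 1e-10)
})

test_that("correlation-mode decomposition is invariant to coordinate rescaling", {
  set.seed(12)
  R <- random_R(9, 5)
  dc <- motion_pca(R, matrix_kind = "correlation")
  Rs <- R
  Rs[, 1] <- 10 * Rs[, 1]   # rescale one coordinate
  dcs <- motion_pca(Rs, matrix_kind = "correlation")
  expect_equal(dc$eigenvalues / dc$total_variance,
               dcs$eigenvalues / dcs$total_variance, tolerance = 1e-8)
  ## covariance-mode is, by contrast, not invariant
  d0 <- motion_pca(R); ds <- motion_pca(Rs)
  expect_gt(abs(d0$eigenvalues[1] / d0$total_variance -
                ds$eigenvalues[1] / ds$total_variance), 1e-4)
  ## zero-variance coordinate is excluded with a warning
  Rz <- R; Rz[, 3] <- 5
  expect_warning(motion_pca(Rz, matrix_kind = "correlation"), "zero-variance")
})

test_that("reference centering changes the spectrum but not the total variance scale", {
  fx <- make_linear_motion_ensemble(m = 10, n = 7, amplitude = 2, seed = 25)
  ens <- fx$ensemble
  d_mean <- motion_pca(ens)
  ens_ref <- fill_gaps(ens, centering = "reference")
  d_ref <- motion_pca(ens_ref)
  ## both explain the same data; reference centering adds the offset term
  expect_gte(d_ref$total_variance, d_mean$total_variance - 1e-10)
  expect_false(isTRUE(all.equal(d_ref$eigenvalues[1], d_mean$eigenvalues[1])))
})
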