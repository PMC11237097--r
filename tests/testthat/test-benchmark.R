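test_that("hull distance matches arithmetic and enumeration oracles", {
  ## inside the hull -> 0
  Tr <- matrix(c(0, 0, 1, 0, 0, 1), 3, 2, byrow = TRUE)
  expect_equal(hull_distance(c(0.2, 0.2), Tr, 9), 0)
  ## 1D training points {0, 3}, p = 5, m = 4 -> (5 - 3) / sqrt(4) = 1
  expect_equal(hull_distance(5, matrix(c(0, 3), 2, 1), 4), 1)
  ## training points and their convex combinations are at distance 0
  set.seed(31)
  P <- matrix(rnorm(12), 6, 2)
  for (i in 1:6) expect_equal(hull_distance(P[i, ], P, 5), 0)
  for (k in 1:5) {
    th <- runif(6); th <- th / sum(th)
    expect_equal(hull_distance(drop(t(P) %*% th), P, 5), 0)
  }
  ## random 2D instances match the face-enumeration oracle
  for (k in 1:25) {
    Tm <- matrix(rnorm(10), 5, 2)
    p <- rnorm(2, sd = 2)
    expect_equal(hull_distance(p, Tm, 7), oracle_hull_distance(p, Tm, 7),
                 tolerance = 1e-8)
  }
  ## and higher-dimensional ones
  for (k in 1:10) {
    Tm <- matrix(rnorm(24), 6, 4)
    p <- rnorm(4, sd = 2)
    expect_equal(hull_distance(p, Tm, 3), oracle_hull_distance(p, Tm, 3),
                 tolerance = 1e-8)
  }
  expect_error(hull_distance(1, matrix(0, 0, 1), 4), "empty")
})

test_that("representation-space clustering uses k = l + 2 and is seeded", {
  fx <- make_linear_motion_ensemble(m = 10, n = 18, amplitude = 3, seed = 33)
  cl <- cluster_for_cv(fx$ensemble, seed = 7)
  expect_equal(cl$l, 1L)
  expect_equal(cl$k, 3L)
  cl2 <- cluster_for_cv(fx$ensemble, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  ## three well-separated 1D blobs are recovered exactly
  set.seed(34)
  blob_centers <- c(-30, 0, 30)
  truth <- rep(1:3, each = 6)
  R <- matrix(0, 18, 6)
  R[, 1] <- blob_centers[truth] + rnorm(18, sd = 0.3)
  dec <- motion_pca(R)
  cl3 <- cluster_for_cv(decomp = dec, seed = 1)
  expect_equal(cl3$k, 3L)
  tab <- table(truth, cl3$labels)
  expect_equal(sort(as.numeric(tab[tab > 0])), rep(6, 3))
  ## too few conformations for k clusters -> informative error
  expect_error(cluster_for_cv(decomp = motion_pca(R[1:2, ]), seed = 1),
               "threshold")
})

test_that("leave-one-cluster-out reconstructs in-span conformations exactly", {
  fx <- make_linear_motion_ensemble(m = 10, n = 15, amplitude = 3, seed = 35)
  cv <- leave_one_cluster_out(fx$ensemble, "pca", seed = 1)
  ## noise-free purely linear ensemble: every held-out conformation lies in
  ## the training linear span
  expect_lt(max(cv$records$rmsd), 1e-6)
  ## every conformation appears exactly once as test
  expect_setequal(cv$records$id, fx$ensemble$member_ids)
  expect_equal(nrow(cv$records), fx$ensemble$n)
  ## the summary fraction is recomputable from the records
  expect_equal(cv$fraction_below_2A, mean(cv$records$rmsd < 2))
})

test_that("extrapolation error grows with hull distance on a curved fixture", {
  ens <- make_arc_ensemble(m = 10, n = 26, radius = 6, arc = 1.4, seed = 23)
  cv <- leave_one_cluster_out(ens, "pca", seed = 1)
  rho <- stats::cor(cv$records$rmsd, cv$records$d_norm, method = "spearman")
  expect_gt(rho, 0)
  ## held-out extreme cluster: largest errors at the largest distances
  worst <- cv$records[which.max(cv$records$rmsd), ]
  expect_gt(worst$d_norm, stats::median(cv$records$d_norm))
})

test_that("kPCA hyperparameter grid search returns the best grid point", {
  ens <- make_arc_ensemble(m = 8, n = 20, radius = 5, arc = 1.2, seed = 37)
  gs <- kpca_grid_search(ens, sigma_factors = c(0.5, 1, 2),
                         alphas = c(1e-8, 1e-4), seed = 1)
  expect_equal(nrow(gs$table), 6L)
  expect_equal(gs$best$mean_rmsd, min(gs$table$mean_rmsd))
  expect_equal(mean(gs$report$records$rmsd), gs$best$mean_rmsd)
  ## nested protocol returns one record per conformation too
  gn <- kpca_grid_search(ens, sigma_factors = c(0.5, 1, 2),
                         alphas = c(1e-8, 1e-4), seed = 1, nested = TRUE)
  expect_equal(nrow(gn$report$records), nrow(gs$report$records))
})

test_that("interpolation trajectories connect cluster centres", {
  hx <- make_hinge_ensemble(m = 20, n = 24, angle_range = pi / 3,
                            noise_sd = 0.02, seed = 39)
  ens <- hx$ensemble
  cl <- cluster_for_cv(ens, seed = 1)
  labs <- cl$labels
  ## pick the two extreme clusters along the first mode
  ord <- tapply(cl$decomp$scores[, 1], labs, mean)
  a <- as.integer(names(which.min(ord)))
  b <- as.integer(names(which.max(ord)))
  mid <- setdiff(sort(unique(labs)), c(a, b))
  known <- ens$R_dense[labs %in% mid, , drop = FALSE]
  traj <- interpolate_states(ens, labs, a, b, "pca", n_points = 21,
                             known = known)
  expect_equal(dim(traj$coordinates), c(21L, 3L * ens$m))
  ## linear trajectory: successive conformations equidistant
  steps <- vapply(seq_len(20), function(i)
    confmotion:::coord_rmsd(traj$coordinates[i, ], traj$coordinates[i + 1, ]), 0)
  expect_lt(max(steps) - min(steps), 1e-8)
  ## a held-out intermediate state is approached mid-trajectory better than
  ## by either endpoint pair
  endpoint_rmsd <- confmotion:::coord_rmsd(traj$coordinates[1, ],
                                           traj$coordinates[21, ])
  expect_lt(min(traj$min_rmsd_to_known), endpoint_rmsd)
  ## endpoints map back near the cluster-centre conformations
  ca_mean <- colMeans(ens$R_dense[labs == a, , drop = FALSE])
  expect_lt(confmotion:::coord_rmsd(traj$coordinates[1, ], ca_mean), 0.5)
  ## degenerate request: identical clusters
  expect_error(interpolate_states(ens, labs, a, a, "pca"), "overlap")
})

test_that("kPCA interpolation stays close to the PCA one in the linear limit", {
  fx <- make_linear_motion_ensemble(m = 8, n = 16, amplitude = 3, seed = 41)
  ens <- fx$ensemble
  cl <- cluster_for_cv(ens, seed = 1)
  labs <- cl$labels
  ord <- tapply(cl$decomp$scores[, 1], labs, mean)
  a <- as.integer(names(which.min(ord)))
  b <- as.integer(names(which.max(ord)))
  t_pca <- interpolate_states(ens, labs, a, b, "pca", n_points = 11)
  md <- max(stats::dist(ens$R_dense))
  t_k <- interpolate_states(ens, labs, a, b, "kpca",
                            spec = kernel_spec("rbf", sigma = 50 * md),
                            preimage_alpha = 1e-10, n_points = 11)
  mid_dev <- confmotion:::coord_rmsd(t_pca$coordinates[6, ], t_k$coordinates[6, ])
  expect_lt(mid_dev, 0.1)
})
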