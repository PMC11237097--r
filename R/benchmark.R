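## Generation benchmark: leave-one-cluster-out cross-validation of linear
## PCA against kernel PCA, convex-hull extrapolation scoring, and
## interpolation trajectories between conformational states.

## Conformation-space RMSD between two 3m coordinate vectors (no refit)
coord_rmsd <- function(a, b) {
  stopifnot(length(a) == length(b))
  sqrt(sum((a - b)^2) / (length(a) / 3))
}

#' Cluster conformations in the PCA representation space
#'
#' k-means clustering of the training projections on the first l linear
#' modes, with k = l + 2, where l is the smallest number of modes explaining
#' `var_threshold` percent of the total positional variance. Seeded and
#' restarted (best of 10), hence deterministic for a given seed.
#'
#' @param ensemble a `conf_ensemble` (or a `motion_pca` via `decomp`).
#' @param decomp optional precomputed `motion_pca` of the ensemble.
#' @param var_threshold variance percentage defining l (default 90).
#' @param seed RNG seed for k-means.
#' @return List with `labels` (1..k), `l`, `k`, `centers`, `decomp`.
#' @export
cluster_for_cv <- function(ensemble = NULL, decomp = NULL, var_threshold = 90,
                           seed = 1L) {
  if (is.null(decomp)) decomp <- motion_pca(ensemble)
  l <- dimensionality(decomp, var_threshold)
  k <- l + 2L
  if (decomp$n < k)
    stop(sprintf("n = %d conformations < k = %d clusters; lower the variance threshold", decomp$n, k))
  P <- decomp$scores[, seq_len(l), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(P, centers = k, nstart = 10L)
  list(labels = km$cluster, l = l, k = k, centers = km$centers,
       decomp = decomp)
}

## Dense working matrix in model (weighted) space plus metadata
ens_model_matrix <- function(ensemble) {
  if (is.null(ensemble$R_dense)) ensemble <- fill_gaps(ensemble)
  w <- if (isTRUE(ensemble$weighting)) ensemble$weights else rep(1, ensemble$m)
  list(R = ensemble$R_dense, w = w, m = ensemble$m,
       ids = ensemble$member_ids)
}

#' Leave-one-cluster-out cross-validation of conformation generation
#'
#' For each conformation cluster: fit the representation model on the other
#' clusters, project each held-out conformation, reconstruct it, and record
#' the reconstruction RMSD (Angstrom) together with the normalised distance
#' of its projection to the convex hull of the training projections in the
#' training-fold PCA space.
#'
#' @param ensemble a gap-filled `conf_ensemble`.
#' @param method `"pca"` or `"kpca"`.
#' @param spec a `kernel_spec` for kPCA (ignored for PCA).
#' @param preimage_alpha ridge regularisation of the kPCA pre-image.
#' @param var_threshold variance percentage defining l (default 90).
#' @param seed k-means seed.
#' @param clusters optional result of [cluster_for_cv()] to reuse labels.
#' @return A `cv_report`: list with `records` (one row per conformation:
#'   id, cluster, rmsd, d_norm, inside_hull), `fraction_below_2A`, `l`,
#'   `method`.
#' @export
leave_one_cluster_out <- function(ensemble, method = c("pca", "kpca"),
                                  spec = NULL, preimage_alpha = 1e-8,
                                  var_threshold = 90, seed = 1L,
                                  clusters = NULL) {
  method <- match.arg(method)
  if (is.null(clusters)) clusters <- cluster_for_cv(ensemble,
                                                    var_threshold = var_threshold,
                                                    seed = seed)
  mm <- ens_model_matrix(ensemble)
  w3 <- rep3(mm$w)
  Xw <- sweep(mm$R, 2L, w3, `*`)   # kPCA operates in the weighted space
  labels <- clusters$labels
  l <- clusters$l
  recs <- list()
  for (cl in sort(unique(labels))) {
    test <- which(labels == cl)
    train <- which(labels != cl)
    if (length(train) < 2L) {
      warning(sprintf("cluster %d leaves %d training conformations; skipped", cl, length(train)))
      next
    }
    fit_lin <- motion_pca(mm$R[train, , drop = FALSE], weights = mm$w)
    l_train <- min(l, length(fit_lin$eigenvalues))
    train_proj <- fit_lin$scores[, seq_len(l_train), drop = FALSE]
    if (method == "kpca") {
      kfit <- kpca_fit(Xw[train, , drop = FALSE], spec, l = l_train,
                       preimage_alpha = preimage_alpha)
    }
    for (i in test) {
      orig <- mm$R[i, ]
      p_lin <- project_conformation(fit_lin, orig, l = l_train,
                                    frame_tol = Inf)
      if (method == "pca") {
        rec <- generate_conformation(fit_lin, p_lin, l = l_train)
      } else {
        p <- kpca_project(kfit, Xw[i, ], l = l_train)
        rec <- kpca_inverse(kfit, p) / w3
      }
      dn <- hull_distance(p_lin, train_proj, mm$m)
      recs[[length(recs) + 1L]] <- data.frame(
        id = mm$ids[i], cluster = cl,
        rmsd = coord_rmsd(rec, orig),
        d_norm = dn, inside_hull = dn == 0,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  structure(list(records = records,
                 fraction_below_2A = mean(records$rmsd < 2),
                 l = l, method = method,
                 spec = if (method == "kpca") spec else NULL),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %s, %d conformations, l = %d>\n",
              x$method, nrow(x$records), x$l))
  cat(sprintf("  reconstruction RMSD: median %.2f A, max %.2f A; %.0f%% below 2 A\n",
              stats::median(x$records$rmsd), max(x$records$rmsd),
              100 * x$fraction_below_2A))
  invisible(x)
}

#' Grid search over kPCA hyperparameters
#'
#' Runs the leave-one-cluster-out cross-validation over a log-grid of kernel
#' widths (multiples of the median pairwise distance of the conformations)
#' and pre-image ridge strengths, returning the pair with the smallest mean
#' reconstruction RMSD. By default the selection uses the test clusters
#' themselves (an optimistic protocol, reporting the best attainable
#' reconstruction per ensemble); `nested = TRUE` instead selects, for each
#' held-out cluster, the hyperparameters that are best on the remaining
#' clusters only.
#'
#' @param ensemble a gap-filled `conf_ensemble`.
#' @param kernel kernel family name.
#' @param sigma_factors multiples of the median pairwise distance to try.
#' @param alphas pre-image regularisation values to try.
#' @param var_threshold,seed passed to [leave_one_cluster_out()].
#' @param nested use the unbiased nested selection protocol?
#' @return List with `best` (spec, alpha, mean RMSD), `table` (all grid
#'   results) and `report` (the `cv_report` at the selected values).
#' @export
kpca_grid_search <- function(ensemble, kernel = "rbf",
                             sigma_factors = c(0.25, 0.5, 1, 2, 4, 8),
                             alphas = 10^c(-10, -8, -6, -4, -2),
                             var_threshold = 90, seed = 1L, nested = FALSE) {
  mm <- ens_model_matrix(ensemble)
  md <- median_pairwise_distance(sweep(mm$R, 2L, rep3(mm$w), `*`))
  clusters <- cluster_for_cv(ensemble, var_threshold = var_threshold,
                             seed = seed)
  grid <- expand.grid(sigma = sigma_factors * md, alpha = alphas)
  reports <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    reports[[g]] <- leave_one_cluster_out(
      ensemble, "kpca", spec = kernel_spec(kernel, sigma = grid$sigma[g]),
      preimage_alpha = grid$alpha[g], clusters = clusters, seed = seed)
  }
  grid$mean_rmsd <- vapply(reports, function(r) mean(r$records$rmsd), 0)
  if (!nested) {
    best <- which.min(grid$mean_rmsd)
    return(list(best = list(spec = kernel_spec(kernel, sigma = grid$sigma[best]),
                            alpha = grid$alpha[best],
                            mean_rmsd = grid$mean_rmsd[best]),
                table = grid, report = reports[[best]]))
  }
  ## nested: per held-out cluster, pick the grid point minimising the mean
  ## RMSD over the other clusters, then take that cluster's records from it
  per_cl <- lapply(reports, function(r) {
    tapply(r$records$rmsd, r$records$cluster, mean)
  })
  cls <- sort(unique(clusters$labels))
  rows <- list()
  for (cl in as.character(cls)) {
    others <- vapply(per_cl, function(x) mean(x[setdiff(names(x), cl)]), 0)
    g <- which.min(others)
    rr <- reports[[g]]$records
    rows[[cl]] <- rr[rr$cluster == as.integer(cl), ]
  }
  records <- do.call(rbind, rows)
  rep_nested <- structure(list(records = records,
                               fraction_below_2A = mean(records$rmsd < 2),
                               l = clusters$l, method = "kpca"),
                          class = "cv_report")
  list(best = NULL, table = grid, report = rep_nested)
}

## ---------------------------------------------------------------------------
## Distance to the convex hull of the training projections

## Exact nearest point of the convex hull of the rows of Tm to p, by a primal
## active-set method on: minimise ||t(Tm) theta - p||^2, theta >= 0,
## sum(theta) = 1. Dimensions here are small (l <= ~10), so the dense KKT
## solves are cheap; MASS::ginv handles affinely dependent training points.
simplex_nearest_point <- function(Tm, p, tol = 1e-10) {
  k <- nrow(Tm)
  if (k == 1L) return(drop(Tm[1L, ]))
  G <- Tm %*% t(Tm)
  b <- drop(Tm %*% p)
  scale <- max(1, max(abs(G)))
  theta <- rep(1 / k, k)
  active <- rep(FALSE, k)
  solve_free <- function(free) {
    kf <- sum(free)
    KKT <- rbind(cbind(2 * G[free, free, drop = FALSE], rep(1, kf)),
                 c(rep(1, kf), 0))
    rhs <- c(2 * b[free], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) MASS::ginv(KKT) %*% rhs)
    drop(sol)[seq_len(kf)]
  }
  for (iter in seq_len(10L * k + 50L)) {
    free <- !active
    th_f <- solve_free(free)
    if (all(th_f >= -tol)) {
      theta[free] <- pmax(th_f, 0)
      theta[active] <- 0
      g <- 2 * (drop(G %*% theta) - b)
      mu <- mean(g[free])
      viol <- which(active & (g - mu < -tol * scale))
      if (length(viol) == 0L) break
      j <- viol[which.min(g[viol])]
      active[j] <- FALSE
    } else {
      idxf <- which(free)
      cur <- theta[idxf]
      dir <- th_f - cur
      blocking <- which(th_f < -tol)
      step <- pmin(1, ifelse(dir < 0, cur / (cur - th_f), 1))
      alpha <- min(step[blocking])
      theta[idxf] <- cur + alpha * dir
      theta[theta < tol] <- 0
      jb <- idxf[blocking[which.min(step[blocking])]]
      active[jb] <- TRUE
      theta[jb] <- 0
    }
  }
  theta <- pmax(theta, 0)
  theta <- theta / sum(theta)
  drop(t(Tm) %*% theta)
}

#' Normalised distance of a projection to the training convex hull
#'
#' Euclidean distance from `p` to the convex hull of the training
#' projections, solved exactly by quadratic programming (the hull is never
#' constructed explicitly), divided by sqrt(m) so that distances are
#' comparable across systems and commensurate with Cartesian RMSDs: in a
#' purely one-dimensional ensemble, two conformations 1 Angstrom RMSD apart
#' are 1 Angstrom apart in normalised representation-space distance.
#'
#' @param p projection vector (length l).
#' @param training_projections k x l matrix of training projections.
#' @param m number of positions of the underlying ensemble.
#' @return The normalised distance in Angstrom (0 for points inside the
#'   hull).
#' @export
hull_distance <- function(p, training_projections, m) {
  Tm <- as.matrix(training_projections)
  if (nrow(Tm) == 0L) stop("empty training set")
  p <- as.numeric(p)
  stopifnot(ncol(Tm) == length(p))
  x <- simplex_nearest_point(Tm, p)
  d <- vnorm(x - p)
  if (d < 1e-9) d <- 0
  d / sqrt(m)
}

## ---------------------------------------------------------------------------
## Interpolation between states

#' Interpolate between two conformational clusters
#'
#' Fits the representation model on the two clusters only, places
#' `n_points` regularly spaced points on the segment between the cluster
#' centres in the representation space, and maps each point back to a
#' conformation. When `known` conformations are supplied, the minimum RMSD
#' of each generated conformation to the known set is reported.
#'
#' @param ensemble a gap-filled `conf_ensemble`.
#' @param labels cluster labels (from [cluster_for_cv()]).
#' @param cluster_a,cluster_b the two cluster labels to interpolate between.
#' @param method `"pca"` or `"kpca"`.
#' @param spec,preimage_alpha kPCA settings.
#' @param n_points number of trajectory points (default 50), endpoints
#'   included.
#' @param l representation dimension (default: the model's).
#' @param known optional matrix of held-out conformations (rows, 3m, in
#'   Angstrom) for the per-point minimum RMSD.
#' @return A `conf_trajectory`: list with `coordinates` (n_points x 3m, in
#'   Angstrom), `t` (completion in [0, 1]), `min_rmsd_to_known`.
#' @export
interpolate_states <- function(ensemble, labels, cluster_a, cluster_b,
                               method = c("pca", "kpca"), spec = NULL,
                               preimage_alpha = 1e-8, n_points = 50L,
                               l = NULL, known = NULL) {
  method <- match.arg(method)
  ia <- which(labels == cluster_a)
  ib <- which(labels == cluster_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty cluster")
  if (length(intersect(ia, ib)) > 0L) stop("clusters overlap")
  mm <- ens_model_matrix(ensemble)
  w3 <- rep3(mm$w)
  idx <- c(ia, ib)
  if (method == "pca") {
    fit <- motion_pca(mm$R[idx, , drop = FALSE], weights = mm$w)
    l <- min(l %||% length(fit$eigenvalues), length(fit$eigenvalues))
    P <- fit$scores[, seq_len(l), drop = FALSE]
  } else {
    Xw <- sweep(mm$R[idx, , drop = FALSE], 2L, w3, `*`)
    fit <- kpca_fit(Xw, spec, l = l, preimage_alpha = preimage_alpha)
    l <- fit$l
    P <- fit$scores[, seq_len(l), drop = FALSE]
  }
  ca <- colMeans(P[seq_along(ia), , drop = FALSE])
  cb <- colMeans(P[length(ia) + seq_along(ib), , drop = FALSE])
  if (vnorm(cb - ca) < 1e-12) stop("cluster centres coincide; degenerate trajectory")
  tt <- seq(0, 1, length.out = n_points)
  pts <- outer(1 - tt, ca) + outer(tt, cb)
  coords <- if (method == "pca") {
    generate_conformation(fit, pts, l = l)
  } else {
    sweep(kpca_inverse(fit, pts), 2L, w3, `/`)
  }
  min_rmsd <- NULL
  if (!is.null(known)) {
    known <- as.matrix(known)
    min_rmsd <- apply(coords, 1L, function(r)
      min(apply(known, 1L, function(kr) coord_rmsd(r, kr))))
  }
  structure(list(coordinates = coords, t = tt, method = method,
                 min_rmsd_to_known = min_rmsd,
                 centers = rbind(a = ca, b = cb)),
            class = "conf_trajectory")
}

#' @export
print.conf_trajectory <- function(x, ...) {
  cat(sprintf("<conf_trajectory: %d points, %s>\n", length(x$t), x$method))
  if (!is.null(x$min_rmsd_to_known))
    cat(sprintf("  min RMSD to known intermediates: best %.2f A\n",
                min(x$min_rmsd_to_known)))
  invisible(x)
}
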