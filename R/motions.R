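## Linear motions: PCA of ensemble Calpha coordinates. The decomposition is
## computed by SVD of the centered (optionally weighted) coordinate matrix,
## never by materialising the 3m x 3m covariance matrix; with n conformations
## over m positions this costs O(n^2 m) and yields at most n non-trivial
## modes, which is what the data support.

#' Principal component analysis of ensemble coordinates
#'
#' Fits the linear-motion model of a conformational ensemble: eigenvectors
#' and eigenvalues of the covariance (or correlation) matrix of the
#' gap-filled, optionally coverage-weighted, Calpha coordinates. Modes are
#' directions of concerted atomic displacement; eigenvalues are positional
#' variances along them.
#'
#' @param x a `conf_ensemble` (gap-filled with [fill_gaps()]; filled
#'   automatically if needed) or a dense n x 3m coordinate matrix.
#' @param matrix_kind `"covariance"` or `"correlation"` (the covariance
#'   normalised per coordinate; zero-variance coordinates are excluded with
#'   a warning).
#' @param centering `"mean"` or `"reference"`; for a matrix input only
#'   `"mean"` is available unless `center` is supplied.
#' @param weights per-position confidence weights (length m); taken from the
#'   ensemble when `x` is a `conf_ensemble`. Coordinates are multiplied by
#'   the weights before centering and decomposition.
#' @param center optional explicit 3m centering conformation (matrix input).
#' @return An object of class `motion_pca` with elements `modes` (3m x K,
#'   orthonormal columns), `eigenvalues` (descending), `center`,
#'   `scores` (n x K projections of the training conformations),
#'   `matrix_kind`, `weights`, `weights_applied`, `m`, `n`,
#'   `total_variance`.
#' @export
motion_pca <- function(x, matrix_kind = c("covariance", "correlation"),
                       centering = NULL, weights = NULL, center = NULL) {
  matrix_kind <- match.arg(matrix_kind)
  if (inherits(x, "conf_ensemble")) {
    if (is.null(x$R_dense)) x <- fill_gaps(x)
    R <- x$R_dense
    weights <- weights %||% (if (isTRUE(x$weighting)) x$weights else rep(1, x$m))
    centering <- centering %||% x$centering
    if (centering == "reference" && is.null(center)) center <- x$center
  } else {
    R <- as.matrix(x)
    centering <- centering %||% "mean"
  }
  n <- nrow(R)
  if (n < 2L) stop("no variance: at least 2 conformations are required")
  if (ncol(R) %% 3L != 0L) stop("coordinate matrix must have 3m columns")
  m <- ncol(R) %/% 3L
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(weights) == m)
  w3 <- rep3(weights)
  Rw <- sweep(R, 2L, w3, `*`)
  ctr <- if (centering == "reference") {
    if (is.null(center)) stop("reference centering requires a center")
    center * w3
  } else colMeans(Rw)
  Rc <- sweep(Rw, 2L, ctr)
  keep <- rep(TRUE, 3L * m)
  scaling <- rep(1, 3L * m)
  if (matrix_kind == "correlation") {
    sdv <- sqrt(colSums(Rc^2) / (n - 1))
    zero <- sdv < 1e-12 * max(sdv, 1e-300)
    if (any(zero)) {
      warning(sprintf("%d zero-variance coordinate(s) excluded from the correlation normalisation", sum(zero)))
      keep <- !zero
    }
    scaling[keep] <- 1 / sdv[keep]
    Rc <- sweep(Rc[, keep, drop = FALSE], 2L, scaling[keep], `*`)
  }
  sv <- svd(Rc)
  lambda <- sv$d^2 / (n - 1)
  K <- max(1L, sum(sv$d > max(sv$d) * 1e-9))
  modes <- matrix(0, 3L * m, K)
  modes[keep, ] <- sv$v[, seq_len(K), drop = FALSE]
  scores <- sv$u[, seq_len(K), drop = FALSE] %*% diag(sv$d[seq_len(K)], K)
  structure(list(
    modes = modes, eigenvalues = lambda[seq_len(K)],
    center = ctr, scores = scores,
    matrix_kind = matrix_kind, centering = centering,
    weights = weights, weights_applied = any(weights != 1),
    coord_kept = keep, m = m, n = n,
    total_variance = sum(lambda)
  ), class = "motion_pca")
}

#' @export
print.motion_pca <- function(x, ...) {
  cat(sprintf("<motion_pca: %d conformations, %d positions, %d modes (%s%s)>\n",
              x$n, x$m, length(x$eigenvalues), x$matrix_kind,
              if (x$weights_applied) ", weighted" else ""))
  frac <- x$eigenvalues / x$total_variance
  k <- min(5L, length(frac))
  cat("Variance fraction of leading modes:",
      paste(sprintf("%.3f", frac[seq_len(k)]), collapse = " "), "\n")
  invisible(x)
}

#' @method summary motion_pca
#' @export
summary.motion_pca <- function(object, thresholds = c(50, 80, 85, 90, 95, 99),
                               ...) {
  dims <- vapply(thresholds, function(t) dimensionality(object, t), 0L)
  out <- list(
    n = object$n, m = object$m,
    dimensionality = setNames(dims, paste0("d", thresholds)),
    top_mode_variance = object$eigenvalues[1] / object$total_variance,
    top_mode_collectivity = collectivity(object$modes[, 1], object$m))
  class(out) <- "summary.motion_pca"
  out
}

#' @export
print.summary.motion_pca <- function(x, ...) {
  cat(sprintf("Linear motions of %d conformations over %d positions\n", x$n, x$m))
  cat("Modes needed to explain 50/80/85/90/95/99% of variance:",
      paste(x$dimensionality, collapse = "/"), "\n")
  cat(sprintf("Top mode: %.1f%% of variance, collectivity %.3f\n",
              100 * x$top_mode_variance, x$top_mode_collectivity))
  invisible(x)
}

#' Scree plot of a motion decomposition
#'
#' @param x a `motion_pca`.
#' @param n_modes number of leading modes to display.
#' @param ... passed to [graphics::barplot()].
#' @method plot motion_pca
#' @export
plot.motion_pca <- function(x, n_modes = min(10L, length(x$eigenvalues)), ...) {
  frac <- x$eigenvalues[seq_len(n_modes)] / x$total_variance
  graphics::barplot(frac, names.arg = seq_len(n_modes),
                    xlab = "mode", ylab = "variance fraction", ...)
  invisible(x)
}

#' Intrinsic dimensionality at a variance threshold
#'
#' The smallest number of leading modes whose cumulative eigenvalues reach
#' `threshold_pct` percent of the total positional variance.
#'
#' @param decomp a `motion_pca`.
#' @param threshold_pct percentage in (0, 100].
#' @return An integer.
#' @export
dimensionality <- function(decomp, threshold_pct = 90) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  cum <- cumsum(decomp$eigenvalues) / decomp$total_variance
  k <- which(cum >= threshold_pct / 100 - 1e-12)
  if (length(k) == 0L) length(decomp$eigenvalues) else k[1]
}

#' Collectivity of a mode
#'
#' Entropy-based degree of collectivity of an eigenvector: with per-atom
#' squared displacements u_i^2 (each atom's three components summed,
#' normalised so that sum(u_i^2) = 1),
#' coll = (1/m) exp(-sum u_i^2 log u_i^2). Equals 1 when all atomic
#' displacement magnitudes are identical and 1/m when a single atom moves.
#'
#' @param mode a 3m-vector (a column of `modes`).
#' @param m number of positions; inferred from the vector length if missing.
#' @return A number in [1/m, 1].
#' @export
collectivity <- function(mode, m = NULL) {
  mode <- as.numeric(mode)
  if (is.null(m)) m <- length(mode) %/% 3L
  stopifnot(length(mode) == 3L * m)
  if (sum(mode^2) < 1e-300) stop("zero mode vector")
  u2 <- rowSums(unflatten_xyz(mode)^2)
  u2 <- u2 / sum(u2)
  nz <- u2 > 0
  (1 / m) * exp(-sum(u2[nz] * log(u2[nz])))
}

#' Root mean square inner product between two mode sets
#'
#' Subspace overlap between the first l modes of two decompositions:
#' sqrt( (1/l) sum_{i,j} (v_i^A . v_j^B)^2 ). 1 for identical subspaces,
#' 0 for orthogonal ones.
#'
#' @param decomp_a,decomp_b `motion_pca` objects (or 3m x K mode matrices)
#'   over the same coordinate space.
#' @param l number of modes to compare (must not exceed either mode count).
#' @return A number in [0, 1].
#' @export
rmsip <- function(decomp_a, decomp_b, l) {
  A <- if (inherits(decomp_a, "motion_pca")) decomp_a$modes else as.matrix(decomp_a)
  B <- if (inherits(decomp_b, "motion_pca")) decomp_b$modes else as.matrix(decomp_b)
  if (nrow(A) != nrow(B)) stop("mode sets live in different coordinate spaces")
  if (l > ncol(A) || l > ncol(B)) stop("l exceeds the available modes")
  ip <- crossprod(A[, seq_len(l), drop = FALSE], B[, seq_len(l), drop = FALSE])
  sqrt(sum(ip^2) / l)
}

## ---------------------------------------------------------------------------
## Projection and generation

## Weight a raw (Angstrom-space) conformation consistently with the training
to_model_space <- function(decomp, r) {
  as.numeric(r) * rep3(decomp$weights)
}

from_model_space <- function(decomp, rw) {
  as.numeric(rw) / rep3(decomp$weights)
}

#' Project a conformation onto the leading modes
#'
#' p = (r - center) V_l for a conformation in the ensemble frame
#' (superimposed, gap-filled, in Angstrom; weighting is applied internally
#' to match the training conformations).
#'
#' @param decomp a `motion_pca`.
#' @param conformation a 3m coordinate vector (or n x 3m matrix).
#' @param l number of modes (default: all).
#' @param frame_tol warn when the conformation's centroid is further than
#'   this from the training centroid (a sign it was not superimposed).
#' @return A length-l vector (or n x l matrix) of mode amplitudes.
#' @export
project_conformation <- function(decomp, conformation, l = NULL,
                                 frame_tol = 10) {
  if (decomp$matrix_kind != "covariance")
    stop("projection is defined for covariance-mode decompositions")
  l <- l %||% length(decomp$eigenvalues)
  V <- decomp$modes[, seq_len(l), drop = FALSE]
  one <- is.null(dim(conformation))
  X <- if (one) matrix(conformation, 1L) else as.matrix(conformation)
  ctr_raw <- unflatten_xyz(from_model_space(decomp, decomp$center))
  off <- max(apply(X, 1L, function(r)
    vnorm(colMeans(unflatten_xyz(r)) - colMeans(ctr_raw))))
  if (off > frame_tol)
    warning(sprintf("conformation centroid offset %.2f A from the training frame; was it superimposed?", off))
  Xw <- sweep(sweep(X, 2L, rep3(decomp$weights), `*`), 2L, decomp$center)
  P <- Xw %*% V
  if (one) drop(P) else P
}

#' Generate a conformation from mode amplitudes
#'
#' r = p V_l' + center, mapped back to Angstrom space (de-weighted when the
#' decomposition was coverage-weighted). With p = 0 this returns the
#' centering conformation.
#'
#' @param decomp a `motion_pca`.
#' @param p amplitude vector of length l (or a matrix of rows).
#' @param l number of modes; defaults to `length(p)`.
#' @return A 3m coordinate vector (or matrix of rows) in Angstrom.
#' @export
generate_conformation <- function(decomp, p, l = NULL) {
  if (decomp$matrix_kind != "covariance")
    stop("generation is defined for covariance-mode decompositions")
  one <- is.null(dim(p))
  P <- if (one) matrix(p, 1L) else as.matrix(p)
  l <- l %||% ncol(P)
  if (ncol(P) != l) stop("amplitude vector length does not match l")
  V <- decomp$modes[, seq_len(l), drop = FALSE]
  Rw <- sweep(P %*% t(V), 2L, decomp$center, `+`)
  out <- sweep(Rw, 2L, rep3(decomp$weights), `/`)
  if (one) drop(out) else out
}

#' @export
predict.motion_pca <- function(object, newdata = NULL, l = NULL, ...) {
  if (is.null(newdata)) {
    l <- l %||% length(object$eigenvalues)
    return(object$scores[, seq_len(l), drop = FALSE])
  }
  project_conformation(object, newdata, l = l)
}
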