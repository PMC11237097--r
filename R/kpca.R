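## Kernel PCA over conformation coordinates, with pre-image reconstruction by
## kernel ridge regression of the training coordinates on their projections.

#' Kernel specification
#'
#' @param name `"rbf"`, `"polynomial"` or `"sigmoid"`.
#' @param sigma kernel width in Angstrom; `NULL` to set it at fit time to the
#'   median pairwise distance of the training conformations.
#' @param c additive offset of the polynomial/sigmoid kernels (default 1).
#' @param degree polynomial degree (default 3).
#' @return A `kernel_spec` object.
#' @export
kernel_spec <- function(name = c("rbf", "polynomial", "sigmoid"),
                        sigma = NULL, c = 1, degree = 3L) {
  name <- match.arg(name)
  if (!is.null(sigma) && sigma <= 0) stop("sigma must be > 0")
  if (degree < 1L) stop("degree must be >= 1")
  structure(list(name = name, sigma = sigma, c = c, degree = degree),
            class = "kernel_spec")
}

#' Kernel matrix between two coordinate sets
#'
#' K_ij = k(a_i, b_j) with the dot-product kernels scaled by 1/(2 sigma^2)
#' and the RBF kernel using the Euclidean distance between conformations.
#'
#' @param A,B matrices with matching column count (rows are conformations).
#' @param spec a `kernel_spec` with `sigma` set.
#' @return A nrow(A) x nrow(B) matrix.
#' @export
kernel_matrix <- function(A, B, spec) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) stop("coordinate dimensions differ")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite coordinates in kernel input")
  if (is.null(spec$sigma)) stop("kernel sigma is not set")
  s2 <- 2 * spec$sigma^2
  if (spec$name == "rbf") {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    exp(-d2 / s2)
  } else if (spec$name == "polynomial") {
    (A %*% t(B) / s2 + spec$c)^spec$degree
  } else {
    tanh(A %*% t(B) / s2 + spec$c)
  }
}

median_pairwise_distance <- function(R) {
  d <- stats::dist(R)
  md <- stats::median(d)
  if (!is.finite(md) || md <= 0) md <- 1
  md
}

#' Fit a kernel PCA model
#'
#' Computes the kernel matrix of the training conformations, double-centers
#' it in feature space, and eigendecomposes it. Components are scaled to
#' unit feature-space norm, so projections of the training conformations
#' equal the eigendecomposition scores. A kernel ridge regressor from the
#' l-dimensional projections back to the input coordinates (same kernel
#' family and width as the kPCA kernel) provides the pre-image map.
#'
#' @param R n x 3m training coordinates (n >= 2).
#' @param spec a `kernel_spec`; a `NULL` sigma is replaced by the median
#'   pairwise distance of `R`.
#' @param l number of components retained for the representation space
#'   (default: all numerically non-null ones).
#' @param preimage_alpha ridge regularisation of the pre-image regressor
#'   (> 0).
#' @return A `kpca_model`.
#' @export
kpca_fit <- function(R, spec, l = NULL, preimage_alpha = 1e-8) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n < 2L) stop("at least 2 training conformations are required")
  if (preimage_alpha <= 0) stop("preimage_alpha must be > 0")
  if (is.null(spec$sigma)) spec$sigma <- median_pairwise_distance(R)
  K <- kernel_matrix(R, R, spec)
  rm_ <- colMeans(K)
  gm <- mean(K)
  Kc <- K - matrix(rm_, n, n, byrow = FALSE) - matrix(rm_, n, n, byrow = TRUE) + gm
  ## rm_ used twice: K is symmetric so row means equal column means
  eig <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-12
  K_rank <- sum(pos)
  if (K_rank == 0L) stop("kernel matrix is numerically null")
  l <- min(l %||% K_rank, K_rank)
  lam <- eig$values[seq_len(K_rank)]
  U <- eig$vectors[, seq_len(K_rank), drop = FALSE]
  alphas <- sweep(U, 2L, sqrt(lam), `/`)   # unit feature-space norm components
  scores <- sweep(U, 2L, sqrt(lam), `*`)   # projections of training data
  model <- structure(list(
    spec = spec, R_train = R, n = n,
    alphas = alphas, lambdas = lam, scores = scores,
    K_col_means = rm_, K_mean = gm,
    l = l, preimage_alpha = preimage_alpha
  ), class = "kpca_model")
  model$preimage <- kpca_train_preimage(model)
  model
}

#' @export
print.kpca_model <- function(x, ...) {
  cat(sprintf("<kpca_model: %s kernel (sigma = %.3g), %d training conformations, l = %d>\n",
              x$spec$name, x$spec$sigma, x$n, x$l))
  invisible(x)
}

kpca_train_preimage <- function(model) {
  P <- model$scores[, seq_len(model$l), drop = FALSE]
  pspec <- model$spec
  Kp <- kernel_matrix(P, P, pspec)
  mu <- colMeans(model$R_train)
  W <- solve(Kp + model$preimage_alpha * diag(nrow(P)),
             sweep(model$R_train, 2L, mu))
  list(P = P, spec = pspec, W = W, mu = mu)
}

#' Project conformations with a fitted kernel PCA
#'
#' Test kernel columns are centered consistently with the training kernel
#' matrix; projections are the sums of the scaled component coefficients
#' against the test kernel values.
#'
#' @param model a `kpca_model`.
#' @param Rnew matrix (or single vector) of conformations in the ensemble
#'   frame.
#' @param l number of components (default: the model's `l`).
#' @return A matrix of projections (rows match `Rnew`).
#' @export
kpca_project <- function(model, Rnew, l = NULL) {
  one <- is.null(dim(Rnew))
  X <- if (one) matrix(Rnew, 1L) else as.matrix(Rnew)
  l <- min(l %||% model$l, ncol(model$alphas))
  Kt <- kernel_matrix(X, model$R_train, model$spec)
  Ktc <- sweep(sweep(Kt, 1L, rowMeans(Kt)), 2L, model$K_col_means) + model$K_mean
  P <- Ktc %*% model$alphas[, seq_len(l), drop = FALSE]
  if (one) drop(P) else P
}

#' Reconstruct conformations from kernel-PCA projections
#'
#' The pre-image problem is solved by kernel ridge regression of the
#' training coordinates on their projections: the returned conformation is
#' the regressor's prediction at `p`.
#'
#' @param model a `kpca_model`.
#' @param p projection vector of length l (or a matrix of rows).
#' @return Coordinates in the input space (vector or matrix matching `p`).
#' @export
kpca_inverse <- function(model, p) {
  one <- is.null(dim(p))
  P <- if (one) matrix(p, 1L) else as.matrix(p)
  if (ncol(P) != model$l)
    stop(sprintf("projection has %d components, model uses l = %d", ncol(P), model$l))
  k <- kernel_matrix(P, model$preimage$P, model$preimage$spec)
  out <- sweep(k %*% model$preimage$W, 2L, model$preimage$mu, `+`)
  if (one) drop(out) else out
}
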