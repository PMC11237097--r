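## Independent oracles and small fixture builders used across the suite.

## Classical unweighted Kabsch fit, written independently of the package's
## superpose_fit (plain centroid + SVD of the cross-covariance).
oracle_kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$u %*% t(s$v)))
  Q <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Xfit <- sweep(Xc %*% Q, 2, cy, `+`)
  list(Xfit = Xfit, rmsd = sqrt(mean(rowSums((Xfit - Y)^2))))
}

## Exact nearest point of conv(rows of Tm) to p by face enumeration: the
## minimiser lies on some face; project onto the affine hull of every subset
## and keep the best feasible (all convex coefficients >= 0) candidate.
oracle_hull_distance <- function(p, Tm, m) {
  Tm <- as.matrix(Tm)
  k <- nrow(Tm)
  best <- Inf
  for (sz in seq_len(k)) {
    subs <- utils::combn(k, sz, simplify = FALSE)
    for (s in subs) {
      S <- Tm[s, , drop = FALSE]
      if (sz == 1L) {
        x <- S[1, ]
        th <- 1
      } else {
        ## affine projection: minimise ||t(S) th - p|| with sum(th) = 1
        A <- rbind(cbind(2 * S %*% t(S), 1), c(rep(1, sz), 0))
        b <- c(2 * S %*% p, 1)
        sol <- tryCatch(solve(A, b), error = function(e) NULL)
        if (is.null(sol)) next
        th <- sol[seq_len(sz)]
        if (any(th < -1e-9)) next
        x <- drop(t(S) %*% th)
      }
      best <- min(best, sqrt(sum((x - p)^2)))
    }
  }
  best / sqrt(m)
}

## Random proper rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## A random coordinate matrix posing as n conformations over m positions
random_R <- function(n, m, sd = 1) matrix(rnorm(n * 3 * m, sd = sd), n, 3 * m)

## Ensemble whose conformations lie on a circular arc in coordinate space:
## a curved one-dimensional manifold (the case where a non-linear model can
## beat the linear one).
make_arc_ensemble <- function(m = 12, n = 24, radius = 6, arc = 1.2,
                              noise_sd = 0.02, seed = 11) {
  set.seed(seed)
  base <- confmotion:::random_ca_trace(m)
  D1 <- matrix(rnorm(3 * m), m, 3); D1 <- D1 / sqrt(sum(D1^2) / m)
  D2 <- matrix(rnorm(3 * m), m, 3)
  D2 <- D2 - D1 * sum(D2 * D1) / sum(D1^2)
  D2 <- D2 / sqrt(sum(D2^2) / m)
  th <- seq(-arc / 2, arc / 2, length.out = n)
  sequence <- confmotion:::random_sequence(m)
  records <- lapply(seq_len(n), function(i) {
    ca <- base + radius * (sin(th[i]) * D1 + (1 - cos(th[i])) * D2) +
      matrix(rnorm(3 * m, sd = noise_sd), m, 3)
    confmotion:::record_from_ca(sprintf("C%03d", i), "A", ca, sequence)
  })
  ids <- vapply(records, function(r) r$id, "")
  msa <- protein_msa(ids, vapply(records, function(r) r$sequence, ""))
  ens <- conf_ensemble(records, msa, weighting = FALSE)
  ens$reference_index <- select_reference(msa)
  ens$superimposed <- TRUE
  fill_gaps(ens)
}

## Tiny manual MSA
msa_of <- function(...) {
  seqs <- c(...)
  protein_msa(sprintf("T%03d_A", seq_along(seqs)), seqs)
}
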