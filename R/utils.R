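## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(x) sqrt(sum(x^2))

unitv <- function(x) {
  n <- vnorm(x)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  x / n
}

## Flatten an m x 3 coordinate block into a length-3m vector (x1,y1,z1,x2,...)
flatten_xyz <- function(mat) as.numeric(t(mat))

## Inverse of flatten_xyz
unflatten_xyz <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

## Expand a per-position vector (length m) to per-coordinate (length 3m)
rep3 <- function(w) rep(w, each = 3L)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x > 1)
    stop(sprintf("'%s' must be a single number in (0, 1]", name))
}
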