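`%||%` <- function(a, b) if (is.null(a)) b else a

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# squared distances between two point sets (n x d, m x d) -> n x m
cross_dist2 <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(as.numeric(a), ncol = 3)
  if (!is.matrix(b)) b <- matrix(as.numeric(b), ncol = 3)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Round half away from zero
#'
#' Fixed-point rounding with the half-up convention used when reporting
#' enrichment factors (base [round()] rounds half to even, so e.g.
#' `round(1.625, 2)` gives 1.62 where 1.63 is wanted for display).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(13 / 8, 2)  # 1.63
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed splitting so each component of a multi-stage
#' simulation gets its own reproducible stream.  Uses a Lehmer-style
#' multiplicative step modulo the Mersenne prime 2^31 - 1, keeping all
#' values in 32-bit integer range.
#'
#' @param seed master seed (non-negative integer).
#' @param index child index (non-negative integer).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, index = 0) {
  m <- 2147483647
  s <- (as.numeric(seed) %% m) + 1
  s <- (s * 48271 + as.numeric(index) * 16807 + 1) %% m
  s <- (s * 48271 + 1) %% m
  as.integer(s %% (m - 2) + 1)
}

# deterministic 31-bit hash of a string, for per-compound seeds
hash31 <- function(s) {
  m <- 2147483647
  h <- 7
  for (k in utf8ToInt(as.character(s))) h <- (h * 131 + k) %% m
  as.integer(h)
}

# run expr with a local RNG state so library code does not disturb the
# caller's stream
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
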