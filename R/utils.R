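#' @keywords internal
"_PACKAGE"

## NULL coalescing, used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible 31-bit seed from a base seed and coordinates
#'
#' Stable FNV-1a-style hash of the base seed plus an arbitrary list of
#' coordinate strings/numbers. Keeps every derived seed in `[0, 2^31 - 1]`
#' so it is always a valid R integer seed. Used to give each simulation
#' cell and replicate its own independent, reproducible RNG stream.
#'
#' @param base integer base seed.
#' @param ... coordinates (coerced to character) identifying the stream.
#' @return a single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(base, ...) {
  key <- paste(c(format(base), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    # 16777619 * h mod 2^31, in double precision without overflow
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483647)
}

## ceiling-rule empirical quantile: smallest order statistic whose
## cumulative proportion is >= p.  Guarantees at least nominal coverage
## on the sample itself (see baseline classifiers).
quantile_ceiling <- function(x, p) {
  stopifnot(p > 0, p <= 1)
  xs <- sort(x)
  k <- ceiling(p * length(xs))
  xs[max(1L, k)]
}

## structured logging: everything diagnostic goes to stderr
scump_log <- function(...) {
  message("[scump] ", ...)
}

## log-sum-exp of two vectors elementwise
lse2 <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

## symmetric check with tolerance
is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}
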