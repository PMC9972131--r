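#' Factor-based coherence and reliability indices (synthetic stand-in)
#'
#' Optional plugin indices inspired by the functional-method family of
#' response-quality statistics: both score how well a respondent's
#' answer vector is explained by a low-dimensional factor structure
#' estimated from the human reference sample. *Response coherence* is
#' the proportion of a respondent's standardized response variance that
#' lies in the retained factor space (range `[0, 1]`); *response
#' reliability* is the Pearson correlation between the observed and the
#' factor-reconstructed response vector (range `[-1, 1]`). Both are
#' suspicion-decreasing: content-responsive humans live near the factor
#' structure, random responders do not.
#'
#' IMPORTANT: the exact published recurrences for these indices are not
#' reproduced here; this implementation is a documented, deterministic
#' stand-in built on iterated principal-axis factoring. It honors the
#' published interface (ranges, orientations, a required dimensionality
#' and an iteration count, defaults 4 and 30) but its numeric values are
#' NOT those of the original indices. The core classifier does not
#' depend on these indices; the default battery is Mahalanobis +
#' person-total.
#'
#' @param z numeric vector of length `d`, or an `n x d` matrix of rows.
#' @param reference a [response_matrix] of reference (human) rows.
#' @param n_dimensions assumed number of latent factors (>= 1, < d).
#' @param n_iterations communality-iteration count for the
#'   principal-axis fit (>= 1).
#' @return `fmt_index()` returns a list with numeric vectors
#'   `coherence` and `reliability`; the single-index wrappers return the
#'   corresponding vector.
#' @export
fmt_index <- function(z, reference, n_dimensions = 4L, n_iterations = 30L) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  stopifnot(inherits(reference, "response_matrix"))
  d <- ncol(reference$values)
  if (n_dimensions < 1L || n_dimensions >= d)
    stop("n_dimensions must be in [1, d-1]")
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (anyNA(reference$values)) stop("impute the reference sample first")
  L <- fmt_loadings(reference$values, n_dimensions, n_iterations)
  mu <- colMeans(reference$values)
  sdv <- apply(reference$values, 2, stats::sd)
  if (any(sdv == 0)) stop("reference sample has zero-variance item(s)")
  zs <- sweep(sweep(z, 2, mu), 2, sdv, "/")
  # projection of each standardized row onto the loading column space
  proj <- zs %*% (L %*% solve(crossprod(L), t(L)))
  tot <- rowSums(zs^2)
  coh <- ifelse(tot > 0, pmin(1, pmax(0, rowSums(proj^2) / tot)), 0)
  rel <- vapply(seq_len(nrow(zs)), function(i) {
    if (stats::sd(zs[i, ]) == 0 || stats::sd(proj[i, ]) == 0) return(0)
    stats::cor(zs[i, ], proj[i, ])
  }, numeric(1))
  list(coherence = as.numeric(coh),
       reliability = pmin(1, pmax(-1, rel)))
}

#' @rdname fmt_index
#' @export
fmt_coherence <- function(z, reference, n_dimensions = 4L, n_iterations = 30L)
  fmt_index(z, reference, n_dimensions, n_iterations)$coherence

#' @rdname fmt_index
#' @export
fmt_reliability <- function(z, reference, n_dimensions = 4L, n_iterations = 30L)
  fmt_index(z, reference, n_dimensions, n_iterations)$reliability

## iterated principal-axis loadings on the reference correlation matrix:
## start with squared multiple correlations on the diagonal, eigen-factor,
## refresh communalities, repeat.  Deterministic (no RNG).
fmt_loadings <- function(rows, k, iters) {
  R <- stats::cor(rows)
  if (anyNA(R)) stop("reference correlation matrix undefined (constant item?)")
  d <- ncol(R)
  Rinv <- tryCatch(solve(R), error = function(e) NULL)
  h2 <- if (is.null(Rinv)) rep(0.5, d) else pmax(0.1, 1 - 1 / diag(Rinv))
  L <- NULL
  for (it in seq_len(iters)) {
    Rh <- R
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    val <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(val), k)
    h2 <- pmin(0.999, pmax(1e-6, rowSums(L^2)))
  }
  L
}
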