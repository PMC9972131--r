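#' Reference statistics for nonresponsivity indices
#'
#' Nonresponsivity indices are outlier statistics: each respondent is
#' scored against a reference sample's item mean vector `m` and item
#' covariance `S` (maximum-likelihood convention, divisor `n`).
#' `reference_from_humans()` uses only the human rows of the
#' calibration sample; `reference_from_calibration()` uses every
#' calibration row (humans and bots). The full-calibration reference
#' is the default throughout the pipeline: with a large simulated bot
#' block it is estimated from thousands of rows, so index values do
#' not degrade out of sample the way a reference built on only
#' `n0tr` humans (often barely exceeding the item count) does.
#'
#' @param cal a [labeled_sample] whose responses are already imputed.
#' @return object of class `reference_stats` with fields `mean` (length
#'   `d`), `covariance` (`d x d`), `source_n`.
#' @export
reference_from_humans <- function(cal) {
  stopifnot(inherits(cal, "labeled_sample"))
  humans <- cal$responses$values[cal$labels == 0L, , drop = FALSE]
  if (nrow(humans) < 2L) stop("need at least 2 human rows for a reference")
  if (anyNA(humans)) stop("impute missing values before computing references")
  reference_stats(humans)
}

#' @rdname reference_from_humans
#' @export
reference_from_calibration <- function(cal) {
  stopifnot(inherits(cal, "labeled_sample"))
  if (anyNA(cal$responses$values))
    stop("impute missing values before computing references")
  reference_stats(cal$responses$values)
}

## build reference_stats from a raw numeric matrix of reference rows
reference_stats <- function(rows) {
  n <- nrow(rows)
  m <- colMeans(rows)
  centred <- sweep(rows, 2, m)
  S <- crossprod(centred) / n          # MLE divisor n, matching the
                                       # class-parameter estimator
  structure(list(mean = m, covariance = S, source_n = n),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> d = %d items, from %d reference rows\n",
              length(x$mean), x$source_n))
  invisible(x)
}

## inverse of the reference covariance, with optional ridge.
## Hard error by default: a singular S usually means a zero-variance
## item among the calibration humans and should be surfaced, not hidden.
ref_precision <- function(ref, ridge = 0) {
  S <- ref$covariance
  if (ridge > 0) S <- S + diag(ridge, nrow(S))
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    v <- diag(ref$covariance)
    zero <- which(v <= .Machine$double.eps)
    hint <- if (length(zero))
      paste0("; zero-variance item(s): ", paste(zero, collapse = ", "))
    else ""
    stop("reference covariance is singular", hint,
         "; rerun with ridge > 0 (e.g. 1e-8) if this is acceptable")
  }
  chol2inv(ch)
}

#' Squared Mahalanobis distance of response vectors
#'
#' `D(z; m, S) = (z - m)' S^{-1} (z - m)`, the squared-distance form
#' (no square root), which is how the index is conventionally defined
#' for nonresponsivity screening. Suspicion-increasing and nonnegative.
#' Taking the square root would be a monotone relabeling and would not
#' change any classification.
#'
#' @param z a numeric vector of length `d`, or an `n x d` matrix of rows.
#' @param ref a `reference_stats` object.
#' @param ridge optional nonnegative ridge added to the covariance
#'   diagonal before inversion (default 0 = hard error on singularity).
#' @return numeric vector of squared distances, one per row of `z`.
#' @export
mahalanobis_distance <- function(z, ref, ridge = 0) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  P <- ref_precision(ref, ridge)
  centred <- sweep(z, 2, ref$mean)
  rowSums((centred %*% P) * centred)
}

#' Person-total correlation
#'
#' The Pearson correlation between a respondent's response vector and
#' the reference item-mean vector `m`. Human responders tend to track
#' the consensus item means, so the index is suspicion-decreasing
#' (smaller / negative values are more suspicious). Rows with zero
#' variance (constant responses) carry no correlation information; they
#' are assigned 0 — the no-information midpoint of [-1, 1] — and
#' flagged via the `"degenerate"` attribute.
#'
#' @param z numeric vector of length `d`, or an `n x d` matrix.
#' @param ref a `reference_stats` object.
#' @return numeric vector in `[-1, 1]` with a logical `"degenerate"`
#'   attribute marking constant rows.
#' @export
person_total_cor <- function(z, ref) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) < 2L) stop("person-total correlation needs d >= 2 items")
  m <- ref$mean
  msd <- stats::sd(m)
  rsd <- apply(z, 1, stats::sd)
  degen <- rsd == 0 | msd == 0
  out <- numeric(nrow(z))
  if (any(!degen))
    out[!degen] <- as.numeric(stats::cor(t(z[!degen, , drop = FALSE]), m))
  if (any(degen)) {
    out[degen] <- 0
    scump_log(sum(degen), " degenerate (constant) row(s) in person-total correlation; set to 0")
  }
  attr(out, "degenerate") <- degen
  out
}

## ---------------------------------------------------------------------
## index registry: each entry computes a whole column of the feature
## matrix and declares its suspicion orientation.  User code can add
## further indices with register_nri().
## ---------------------------------------------------------------------
.nri_registry <- new.env(parent = emptyenv())

#' Register a nonresponsivity index
#'
#' Extension point for additional indices (even-odd consistency,
#' person-fit statistics, ...). The built-ins are `"mahalanobis"`,
#' `"person_total"`, `"fmt_coherence"`, `"fmt_reliability"`.
#'
#' @param name index name used in `indices =` arguments.
#' @param fun `function(values, ref, reference_rm, settings)` returning
#'   one numeric value per row of `values`.
#' @param orientation `"increasing"` (larger = more suspicious) or
#'   `"decreasing"`.
#' @return `name`, invisibly.
#' @export
register_nri <- function(name, fun, orientation = c("increasing", "decreasing")) {
  orientation <- match.arg(orientation)
  assign(name, list(fun = fun, orientation = orientation), envir = .nri_registry)
  invisible(name)
}

#' Names of registered nonresponsivity indices
#' @return character vector.
#' @export
nri_names <- function() ls(.nri_registry)

## built-in index registrations (run at load time; see zzz.R)
register_builtin_nris <- function() {
  register_nri("mahalanobis", function(values, ref, reference_rm, settings)
    mahalanobis_distance(values, ref, ridge = settings$ridge %||% 0),
    orientation = "increasing")
  register_nri("person_total", function(values, ref, reference_rm, settings) {
    r <- person_total_cor(values, ref)
    attributes(r) <- NULL
    r
  }, orientation = "decreasing")
  register_nri("fmt_coherence", function(values, ref, reference_rm, settings)
    fmt_index(values, reference_rm,
              n_dimensions = settings$n_dimensions %||% 4L,
              n_iterations = settings$n_iterations %||% 30L)$coherence,
    orientation = "decreasing")
  register_nri("fmt_reliability", function(values, ref, reference_rm, settings)
    fmt_index(values, reference_rm,
              n_dimensions = settings$n_dimensions %||% 4L,
              n_iterations = settings$n_iterations %||% 30L)$reliability,
    orientation = "decreasing")
}

#' Feature matrix of nonresponsivity indices
#'
#' Transforms every respondent row of `rm` into a vector of index
#' values, one column per requested index, with per-column suspicion
#' orientation recorded. Column order follows the request.
#'
#' @param rm an imputed [response_matrix] to score.
#' @param ref `reference_stats` from the calibration humans.
#' @param reference_rm optional [response_matrix] of the raw reference
#'   rows (required by the factor-based indices).
#' @param indices character vector of registered index names; default
#'   `c("mahalanobis", "person_total")` — the core battery, sufficient
#'   for the whole pipeline.
#' @param settings named list of per-index settings (`ridge`,
#'   `n_dimensions`, `n_iterations`).
#' @return object of class `feature_matrix`: fields `values`
#'   (`n x J` numeric), `index_names`, `orientations`.
#' @export
featurize <- function(rm, ref, reference_rm = NULL,
                      indices = c("mahalanobis", "person_total"),
                      settings = list()) {
  stopifnot(inherits(rm, "response_matrix"))
  if (anyNA(rm$values)) stop("impute missing values before featurizing")
  unknown <- setdiff(indices, nri_names())
  if (length(unknown))
    stop("unknown index name(s): ", paste(unknown, collapse = ", "))
  cols <- lapply(indices, function(nm) {
    entry <- get(nm, envir = .nri_registry)
    v <- entry$fun(rm$values, ref, reference_rm, settings)
    if (any(!is.finite(v)))
      stop("non-finite values produced by index '", nm, "'")
    v
  })
  values <- do.call(cbind, cols)
  colnames(values) <- indices
  feature_matrix(values, indices,
                 vapply(indices, function(nm)
                   get(nm, envir = .nri_registry)$orientation, character(1)))
}

#' Construct a feature matrix directly
#'
#' @param values `n x J` numeric matrix of index values.
#' @param index_names length-`J` character vector.
#' @param orientations length-`J` vector of `"increasing"`/`"decreasing"`.
#' @return a `feature_matrix` object.
#' @export
feature_matrix <- function(values, index_names = colnames(values),
                           orientations = rep("increasing", ncol(values))) {
  values <- as.matrix(values)
  if (ncol(values) < 1L) stop("feature matrix needs J >= 1 columns")
  if (any(!is.finite(values))) stop("feature matrix has non-finite values")
  index_names <- index_names %||% paste0("f", seq_len(ncol(values)))
  stopifnot(length(index_names) == ncol(values),
            length(orientations) == ncol(values),
            all(orientations %in% c("increasing", "decreasing")))
  colnames(values) <- index_names
  structure(list(values = values, index_names = as.character(index_names),
                 orientations = as.character(orientations)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d respondents x %d indices: %s\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s (%s)", x$index_names, x$orientations),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Recode all indices to suspicion-increasing form
#'
#' Suspicion-decreasing columns are negated and relabelled increasing;
#' already-increasing columns are untouched. Threshold-based
#' classifiers (the univariate union rule) require this common
#' orientation.
#'
#' @param fm a `feature_matrix`.
#' @return a `feature_matrix` with all orientations `"increasing"`.
#' @export
to_suspicion_increasing <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  dec <- fm$orientations == "decreasing"
  vals <- fm$values
  vals[, dec] <- -vals[, dec, drop = FALSE]
  feature_matrix(vals, fm$index_names, rep("increasing", ncol(vals)))
}

#' Write a feature matrix to CSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) carries index names, orientations,
#' settings and reference provenance so a feature file is
#' self-describing.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV output path.
#' @param settings,provenance optional lists echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path, settings = list(), provenance = list()) {
  utils::write.table(fm$values, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  side <- list(index_names = fm$index_names, orientations = fm$orientations,
               settings = settings, provenance = provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
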