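#' Univariate union-rule cutoffs at a nominal specificity
#'
#' The traditional screening recipe: for each index (in
#' suspicion-increasing form), take its nominal-level percentile over
#' the calibration HUMANS as a threshold. The empirical quantile uses
#' the ceiling rule — the smallest order statistic whose cumulative
#' proportion reaches the nominal level — which guarantees at least
#' nominal coverage on the calibration humans themselves.
#'
#' @param cal_features_increasing a [feature_matrix] for the
#'   calibration rows, all orientations `"increasing"` (see
#'   [to_suspicion_increasing()]).
#' @param labels 0/1 calibration labels (thresholds use humans only).
#' @param nominal_specificity nominal level in `(0, 1]`, default 0.99.
#' @return object of class `univariate_cutoffs`: `thresholds` (one per
#'   column), `index_names`, `nominal_specificity`.
#' @export
fit_univariate_union <- function(cal_features_increasing, labels,
                                 nominal_specificity = 0.99) {
  fm <- cal_features_increasing
  stopifnot(inherits(fm, "feature_matrix"))
  if (any(fm$orientations != "increasing"))
    stop("recode features with to_suspicion_increasing() first")
  labels <- as.integer(labels)
  humans <- fm$values[labels == 0L, , drop = FALSE]
  if (nrow(humans) == 0L) stop("no human rows in the calibration sample")
  thresholds <- apply(humans, 2, quantile_ceiling, p = nominal_specificity)
  structure(list(thresholds = thresholds, index_names = fm$index_names,
                 nominal_specificity = nominal_specificity),
            class = "univariate_cutoffs")
}

#' Predict with the univariate union rule
#'
#' Flags a respondent iff they exceed the threshold on ANY index
#' (strict inequality; values exactly at a threshold are spared).
#' Because each index is a separate test, the realized specificity on
#' fresh humans falls below the nominal level as indices are added —
#' the multiple-testing attenuation the union rule is known for.
#'
#' @param fm a suspicion-increasing [feature_matrix], columns aligned
#'   with the fitted cutoffs.
#' @param cuts a `univariate_cutoffs` object.
#' @return a [classification_report]; `scores` is the count of
#'   thresholds exceeded (threshold 0).
#' @export
predict_univariate_union <- function(fm, cuts) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cuts, "univariate_cutoffs"))
  if (!identical(fm$index_names, cuts$index_names))
    stop("feature columns do not match the fitted cutoffs")
  if (any(fm$orientations != "increasing"))
    stop("recode features with to_suspicion_increasing() first")
  exceed <- sweep(fm$values, 2, cuts$thresholds, ">")
  n_exceed <- rowSums(exceed)
  classification_report(predicted = as.integer(n_exceed > 0),
                        scores = n_exceed, threshold = 0)
}

#' Specificity-calibrated Mahalanobis cutoff in feature space
#'
#' A multivariate specificity-calibrated baseline: score each target
#' row by its squared Mahalanobis distance from the calibration-human
#' feature cloud, and flag rows whose distance exceeds the
#' nominal-level ceiling quantile of the calibration humans' own
#' distances. Unlike the adaptive mixture classifier, the cutoff
#' ignores the target's contamination rate entirely.
#'
#' @param cal_features calibration [feature_matrix] (any orientation;
#'   the distance is orientation-free).
#' @param labels 0/1 calibration labels.
#' @param target_features target [feature_matrix], same columns.
#' @param nominal_specificity nominal level in `(0, 1]`, default 0.99.
#' @param ridge optional ridge for the human feature covariance.
#' @return a [classification_report] with `scores` = squared feature
#'   distances, `threshold` = tau; also fields `cutoff` (an object of
#'   class `mahalanobis_cutoff`).
#' @export
fit_predict_mahalanobis_cutoff <- function(cal_features, labels,
                                           target_features,
                                           nominal_specificity = 0.99,
                                           ridge = 0) {
  stopifnot(inherits(cal_features, "feature_matrix"),
            inherits(target_features, "feature_matrix"))
  if (!identical(cal_features$index_names, target_features$index_names))
    stop("calibration and target feature columns differ")
  labels <- as.integer(labels)
  humans <- cal_features$values[labels == 0L, , drop = FALSE]
  J <- ncol(humans)
  if (nrow(humans) < J + 1L)
    stop("need at least J+1 calibration humans for a feature covariance")
  ref <- reference_stats(humans)
  d_cal <- mahalanobis_distance(humans, ref, ridge = ridge)
  tau <- quantile_ceiling(d_cal, nominal_specificity)
  d_tgt <- mahalanobis_distance(target_features$values, ref, ridge = ridge)
  report <- classification_report(predicted = as.integer(d_tgt > tau),
                                  scores = d_tgt, threshold = tau)
  report$cutoff <- structure(list(mean = ref$mean, covariance = ref$covariance,
                                  threshold = tau,
                                  nominal_specificity = nominal_specificity),
                             class = "mahalanobis_cutoff")
  report
}
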