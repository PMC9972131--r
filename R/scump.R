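## ---------------------------------------------------------------------
## multivariate Gaussian log-density via Cholesky.  Densities are never
## exponentiated directly: with several indices and far outliers the raw
## density underflows, so everything downstream works with log phi and
## clipped density ratios.
## ---------------------------------------------------------------------
dmvnorm_log <- function(x, mean, cov, ridge = 0) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  J <- ncol(x)
  if (ridge > 0) cov <- cov + diag(ridge, J)
  ch <- tryCatch(chol(cov), error = function(e)
    stop("class covariance is not positive definite; consider ridge > 0"))
  centred <- sweep(x, 2, mean)
  # solve R'u = z  ->  quadratic form = ||u||^2
  u <- backsolve(ch, t(centred), transpose = TRUE)
  q <- colSums(u^2)
  -0.5 * (J * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

#' Per-class Gaussian feature parameters from a calibration sample
#'
#' Maximum-likelihood estimates within each class: per-class mean is the
#' arithmetic mean and per-class covariance is the average outer product
#' of deviations with divisor `n_class` (no `n - 1` correction).
#'
#' @param cal_features a [feature_matrix] for the calibration rows.
#' @param labels binary 0/1 labels, one per row (0 = human, 1 = bot).
#' @param ridge optional nonnegative ridge added to each covariance
#'   diagonal (default 0 = hard error if one is singular).
#' @return object of class `gaussian_class_params` with fields `mean0`,
#'   `cov0`, `mean1`, `cov1`, `n0`, `n1`, `index_names`, `ridge`.
#' @export
estimate_class_params <- function(cal_features, labels, ridge = 0) {
  stopifnot(inherits(cal_features, "feature_matrix"))
  labels <- as.integer(labels)
  X <- cal_features$values
  if (length(labels) != nrow(X)) stop("labels length mismatch")
  J <- ncol(X)
  fit1 <- function(k) {
    rows <- X[labels == k, , drop = FALSE]
    if (nrow(rows) == 0L) stop("class ", k, " absent from calibration sample")
    mu <- colMeans(rows)
    centred <- sweep(rows, 2, mu)
    list(mean = mu, cov = crossprod(centred) / nrow(rows), n = nrow(rows))
  }
  h <- fit1(0L); b <- fit1(1L)
  # fewer than J+1 rows in a class necessarily leaves its covariance
  # singular; the estimates are still the printed MLEs, so they are
  # returned, and the singularity errors when densities are evaluated
  # (dmvnorm via Cholesky) unless a ridge is supplied
  if (min(h$n, b$n) < J + 1L && ridge == 0)
    scump_log("a class has fewer than J+1 rows; its covariance is singular ",
              "and density evaluation will fail without a ridge")
  structure(list(mean0 = h$mean, cov0 = h$cov, mean1 = b$mean, cov1 = b$cov,
                 n0 = h$n, n1 = b$n, index_names = cal_features$index_names,
                 ridge = ridge),
            class = "gaussian_class_params")
}

#' @export
print.gaussian_class_params <- function(x, ...) {
  cat(sprintf("<gaussian_class_params> J = %d indices; n0 = %d humans, n1 = %d bots\n",
              length(x$mean0), x$n0, x$n1))
  invisible(x)
}

## per-row class log-densities under fitted params
class_logdens <- function(features, params) {
  X <- if (inherits(features, "feature_matrix")) features$values else features
  if (!is.null(params$index_names) && !is.null(colnames(X)) &&
      !identical(colnames(X), params$index_names))
    stop("feature columns do not match the fitted index battery")
  list(log0 = dmvnorm_log(X, params$mean0, params$cov0, params$ridge),
       log1 = dmvnorm_log(X, params$mean1, params$cov1, params$ridge))
}

## clipped density ratios r_i = phi1/phi0, computed in log space
density_ratios <- function(log1, log0) {
  if (any(!is.finite(log1) & !is.finite(log0)))
    stop("a target row has zero density under BOTH classes: ",
         "numerical underflow upstream or an impossible feature point; ",
         "inspect the offending rows before classification")
  pmin(pmax(exp(log1 - log0), 1e-300), 1e300)
}

#' Score function of the mixture log-likelihood in the mixing proportion
#'
#' First derivative of `l(lambda) = sum_i log(lambda*phi1_i +
#' (1-lambda)*phi0_i)`, evaluated stably from per-observation density
#' ratios: `sum_i (r_i - 1) / (lambda*r_i + 1 - lambda)` with
#' `r_i = phi1_i/phi0_i`. The likelihood is concave, so the score is
#' nonincreasing in `lambda`.
#'
#' @param lambda mixing proportion in `[0, 1]`.
#' @param dens1,dens0 per-row class densities (either raw densities or,
#'   preferably, via `log = TRUE`, log-densities).
#' @param log if `TRUE` (default) `dens1`/`dens0` are log-densities.
#' @return the scalar score `dl/dlambda` at `lambda`.
#' @export
mixture_score <- function(lambda, dens1, dens0, log = TRUE) {
  stopifnot(lambda >= 0, lambda <= 1, length(dens1) == length(dens0))
  if (!log) {
    if (any(dens1 < 0 | dens0 < 0)) stop("densities must be nonnegative")
    if (any(dens1 == 0 & dens0 == 0))
      stop("an observation has zero density under both classes")
    dens1 <- log(dens1); dens0 <- log(dens0)
  }
  r <- density_ratios(dens1, dens0)
  sum((r - 1) / (lambda * r + 1 - lambda))
}

## mixture log-likelihood at lambda, from log-densities (log-sum-exp)
mixture_loglik <- function(lambda, log1, log0) {
  if (lambda == 0) return(sum(log0))
  if (lambda == 1) return(sum(log1))
  sum(lse2(log(lambda) + log1, log(1 - lambda) + log0))
}

#' Unsupervised maximum-likelihood contamination rate
#'
#' With the two class feature distributions fixed at their supervised
#' estimates, the mixture has a single free parameter: the bot
#' prevalence `lambda` in the target sample. Its log-likelihood is
#' concave, so the maximizer is found from the score: if the score has
#' the same sign at both endpoints, the maximizing endpoint is returned
#' (`score(0) <= 0` implies 0, `score(1) >= 0` implies 1); otherwise the
#' root is bracketed in `[0, 1]` and found by bisection.
#'
#' @param target_features a [feature_matrix] for the unlabeled target
#'   sample (or a bare numeric matrix).
#' @param params a `gaussian_class_params` fit.
#' @param tol bisection tolerance on `lambda` (default 1e-8).
#' @param max_iter bisection iteration cap (default 200).
#' @return object of class `gaussian_mixture_fit`: fields `params`,
#'   `lambda_hat`, `loglik_at_max`, `iterations`, `tol`, `endpoint`
#'   (TRUE if an endpoint was selected), `log1`, `log0` (per-row class
#'   log-densities, reused by the Bayes classifier).
#' @export
estimate_lambda <- function(target_features, params, tol = 1e-8,
                            max_iter = 200L) {
  ld <- class_logdens(target_features, params)
  log1 <- ld$log1; log0 <- ld$log0
  if (any(!is.finite(log1) & !is.finite(log0)))
    stop("target rows impossible under both classes; see mixture_score()")
  r <- density_ratios(log1, log0)
  score <- function(l) sum((r - 1) / (l * r + 1 - l))
  s0 <- score(0); s1 <- score(1)
  endpoint <- FALSE; iter <- 0L
  if (s0 <= 0) {            # concave: score nonincreasing, max at 0
    lambda <- 0; endpoint <- TRUE
  } else if (s1 >= 0) {     # max at 1
    lambda <- 1; endpoint <- TRUE
  } else {
    lo <- 0; hi <- 1
    while (hi - lo > tol && iter < max_iter) {
      mid <- (lo + hi) / 2
      if (score(mid) > 0) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
    lambda <- (lo + hi) / 2
  }
  structure(list(params = params, lambda_hat = lambda,
                 loglik_at_max = mixture_loglik(lambda, log1, log0),
                 iterations = iter, tol = tol, endpoint = endpoint,
                 n_target = length(log1), log1 = log1, log0 = log0),
            class = "gaussian_mixture_fit")
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat(sprintf("<gaussian_mixture_fit> lambda_hat = %.4f (%s, %d bisection steps), n = %d, loglik = %.3f\n",
              x$lambda_hat, if (x$endpoint) "endpoint" else "interior",
              x$iterations, x$n_target, x$loglik_at_max))
  invisible(x)
}

#' Bayes classification of the target sample under the fitted mixture
#'
#' Flags respondent `i` iff `lambda_hat * phi1(i) > (1 - lambda_hat) *
#' phi0(i)` (strict inequality; ties are spared), evaluated in log
#' space. Also returns the suspicion-increasing composite score
#' `v_i = lambda_hat*phi1(i) - (1-lambda_hat)*phi0(i)` (threshold 0)
#' and the per-row posterior probability of being a bot. For ranking
#' purposes the composite is monotone in the posterior.
#'
#' @param target_features a [feature_matrix] to classify; `NULL`
#'   (default in the pipeline) reuses the cached log-densities of the
#'   sample the fit was estimated on.
#' @param fit a `gaussian_mixture_fit`.
#' @return a [classification_report] with fields `predicted`, `scores`
#'   (posterior log-odds composite), `posterior`, `threshold = 0`,
#'   `lambda_hat`.
#' @export
bayes_classify <- function(target_features = NULL, fit) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (is.null(target_features)) {         # reuse the estimation target
    log1 <- fit$log1; log0 <- fit$log0
  } else {
    ld <- class_logdens(target_features, fit$params)
    log1 <- ld$log1; log0 <- ld$log0
  }
  lam <- fit$lambda_hat
  # posterior log-odds of bot; lambda endpoints give -Inf/+Inf cleanly
  lo1 <- if (lam > 0) log(lam) + log1 else rep(-Inf, length(log1))
  lo0 <- if (lam < 1) log(1 - lam) + log0 else rep(-Inf, length(log0))
  predicted <- as.integer(lo1 > lo0)           # strict: ties spared
  logodds <- lo1 - lo0
  posterior <- 1 / (1 + exp(-logodds))
  posterior[is.nan(posterior)] <- 0.5          # both -Inf cannot occur (checked upstream)
  classification_report(predicted = predicted, scores = logodds,
                        threshold = 0, posterior = posterior,
                        lambda_hat = lam)
}

#' Fit-and-classify pipeline
#'
#' End-to-end run of the two-stage procedure: impute both samples,
#' build the human reference, featurize calibration and target, fit the
#' per-class Gaussians (supervised), estimate the contamination rate on
#' the target by maximum likelihood (unsupervised), and classify with
#' the Bayes rule. Because the cutoff depends on `lambda_hat`, the
#' prediction for each target row depends on the whole target sample:
#' the classifier adapts itself to the contamination at hand.
#'
#' @param cal a [labeled_sample] (stratified calibration sample).
#' @param target a [response_matrix] of unlabeled target respondents.
#' @param indices index battery (default Mahalanobis + person-total).
#' @param settings per-index settings list (see [featurize()]).
#' @param reference `"calibration"` (default) scores indices against
#'   the whole calibration sample; `"humans"` against the calibration
#'   humans only (see [reference_from_humans()] for the trade-off).
#' @param ridge ridge for class covariances (default 0).
#' @param tol tolerance for the contamination-rate bisection.
#' @return list with `report` (a [classification_report]), `fit`
#'   (the `gaussian_mixture_fit`), `reference`, `cal_features`,
#'   `target_features`.
#' @examples
#' set.seed(1)
#' hum <- generate_humans(human_model_grm(seed = 1), n = 120, seed = 2)
#' bot <- generate_bots(bot_model("uniform"), n = 2000, d = 32, seed = 3)
#' cal <- labeled_sample(rm_stack(hum, bot), rep(0:1, c(120, 2000)))
#' tgt <- rm_stack(generate_humans(human_model_grm(seed = 1), 50, seed = 4),
#'                 generate_bots(bot_model("uniform"), 50, d = 32, seed = 5))
#' res <- scump(cal, tgt)
#' res$fit$lambda_hat
#' @export
scump <- function(cal, target, indices = c("mahalanobis", "person_total"),
                  settings = list(), reference = c("calibration", "humans"),
                  ridge = 0, tol = 1e-8) {
  stopifnot(inherits(cal, "labeled_sample"),
            inherits(target, "response_matrix"))
  reference <- match.arg(reference)
  cal_rm <- impute_middle(cal$responses)
  cal <- labeled_sample(cal_rm, cal$labels)
  target <- impute_middle(target)
  if (reference == "calibration") {
    ref <- reference_from_calibration(cal)
    ref_rm <- cal_rm
  } else {
    ref <- reference_from_humans(cal)
    ref_rm <- rm_subset(cal_rm, cal$labels == 0L)
  }
  cal_f <- featurize(cal_rm, ref, ref_rm, indices, settings)
  tgt_f <- featurize(target, ref, ref_rm, indices, settings)
  params <- estimate_class_params(cal_f, cal$labels, ridge = ridge)
  fit <- estimate_lambda(tgt_f, params, tol = tol)
  report <- bayes_classify(tgt_f, fit)
  list(report = report, fit = fit, reference = ref,
       cal_features = cal_f, target_features = tgt_f)
}

#' Stack two response matrices (rows)
#'
#' Convenience for building calibration/target samples from generated
#' human and bot blocks with matching items and category bounds.
#'
#' @param a,b [response_matrix] objects with identical items.
#' @return a [response_matrix].
#' @export
rm_stack <- function(a, b) rm_bind(a, b)

#' Serialize a fitted model to JSON
#'
#' Stores per-class means/covariances, the estimated contamination
#' rate, the index battery and settings, and a provenance hash of the
#' calibration feature values, so `scump predict` can verify it is
#' applied to a compatible configuration.
#'
#' @param params a `gaussian_class_params`.
#' @param fit optional `gaussian_mixture_fit` (adds `lambda_hat`).
#' @param path output path.
#' @param settings settings list echoed into the file.
#' @param provenance optional provenance list (e.g. calibration hash).
#' @return `path`, invisibly.
#' @export
write_scump_model <- function(params, path, fit = NULL, settings = list(),
                              provenance = list()) {
  obj <- list(schema = "scump-model/1",
              index_names = params$index_names,
              mean0 = params$mean0, cov0 = params$cov0,
              mean1 = params$mean1, cov1 = params$cov1,
              n0 = params$n0, n1 = params$n1, ridge = params$ridge,
              lambda_hat = if (!is.null(fit)) fit$lambda_hat else NULL,
              settings = settings, provenance = provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a fitted model written by [write_scump_model()]
#' @param path model JSON path.
#' @return a `gaussian_class_params` with attribute `"model_meta"`.
#' @export
read_scump_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "scump-model/1"))
    stop("unrecognized model schema: ", obj$schema %||% "<none>")
  params <- structure(list(
    mean0 = as.numeric(obj$mean0), cov0 = as.matrix(obj$cov0),
    mean1 = as.numeric(obj$mean1), cov1 = as.matrix(obj$cov1),
    n0 = obj$n0, n1 = obj$n1,
    index_names = as.character(obj$index_names),
    ridge = obj$ridge %||% 0), class = "gaussian_class_params")
  attr(params, "model_meta") <- obj[c("lambda_hat", "settings", "provenance")]
  params
}
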