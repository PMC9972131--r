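#' Bot response model
#'
#' A bot answers every item with an independent draw from a fixed
#' probability mass function over the categories: `"uniform"` puts mass
#' `1/K` on each category; `"middle"` prefers the middle category with
#' pmf `(0.1, 0.2, 0.4, 0.2, 0.1)` on a 5-point scale; `"custom"` takes
#' any pmf.
#'
#' @param name `"uniform"`, `"middle"` or `"custom"`.
#' @param K number of categories (default 5).
#' @param pmf custom pmf over categories `1..K` (required for
#'   `"custom"`); must be nonnegative and sum to 1.
#' @return object of class `bot_model`.
#' @export
bot_model <- function(name = c("uniform", "middle", "custom"), K = 5L,
                      pmf = NULL) {
  name <- match.arg(name)
  K <- as.integer(K)
  pmf <- switch(name,
    uniform = rep(1 / K, K),
    middle = {
      if (K != 5L) stop("the middle-preferring pmf is defined for K = 5")
      c(0.1, 0.2, 0.4, 0.2, 0.1)
    },
    custom = {
      if (is.null(pmf)) stop("custom bot model needs an explicit pmf")
      pmf
    })
  if (length(pmf) != K) stop("pmf length must equal K")
  if (any(pmf < 0) || abs(sum(pmf) - 1) > 1e-12)
    stop("pmf must be nonnegative and sum to 1")
  structure(list(name = name, K = K, pmf = pmf), class = "bot_model")
}

#' Generate bot response rows
#'
#' @param model a [bot_model].
#' @param n number of bot rows.
#' @param d number of items.
#' @param seed integer seed (local to this call).
#' @return a [response_matrix] of `n x d` i.i.d. categorical draws.
#' @export
generate_bots <- function(model, n, d, seed = NULL) {
  stopifnot(inherits(model, "bot_model"), n >= 1, d >= 2)
  if (!is.null(seed)) {
    old <- local_rng(seed); on.exit(restore_rng(old))
  }
  vals <- matrix(sample.int(model$K, n * d, replace = TRUE, prob = model$pmf),
                 nrow = n)
  response_matrix(vals, categories = c(1L, model$K))
}

#' Multidimensional graded-response human model
#'
#' Synthetic stand-in for a policed human sample: latent trait vectors
#' are drawn from a correlated multivariate normal and mapped to
#' ordered categories through a logistic graded-response link,
#' `P(Z >= k | theta) = plogis(a * (theta_f - b_{k-1}))`. The default
#' emulates a 32-item, 4-factor, 5-point instrument (8 items per
#' factor, inter-factor correlation 0.3, discriminations U(1, 2.5));
#' per-item difficulty locations are N(0, 0.9) and the K-1 ordered
#' thresholds are sorted N(location, 1.5) draws; a 10% minority of
#' respondents carries partial careless severity. The defaults were
#' calibrated once so that item means spread over roughly 2-4 with
#' item sds near 1.3 (the summary statistics typical of published
#' multi-scale Likert instruments) and so that the separation between
#' humans and uniform bots in index space sits in the published
#' regime (composite AUC around 0.95).
#' The model is deliberately shaped like a multi-scale
#' humor/personality questionnaire but NOT calibrated to any real data
#' set. A `"resample"` variant draws rows with replacement from a
#' user-supplied response matrix (e.g. a real survey sample).
#'
#' @param n_items number of items (default 32).
#' @param n_factors number of correlated latent factors (default 4;
#'   items are split evenly across factors).
#' @param factor_cor common inter-factor correlation (default 0.3) or a
#'   full correlation matrix.
#' @param K number of response categories (default 5).
#' @param discrimination_range range for the uniform draw of item
#'   discriminations (default `c(1.0, 2.5)`).
#' @param location_sd sd of the per-item difficulty location (default
#'   0.9; governs how much item means differ across items).
#' @param threshold_sd sd of the threshold draws around the item
#'   location (default 1.5; governs item response spread).
#' @param careless_prob fraction of humans with nonzero careless
#'   severity (default 0.1).
#' @param max_severity upper bound of the uniform severity draw for
#'   the careless minority (default 0.6): severity is the per-item
#'   probability of a content-nonresponsive uniform answer, so real
#'   "policed" human pools keep a low-grade careless tail without any
#'   fully random rows.
#' @param seed seed fixing the item parameters (so a model is a fixed
#'   "population"; response draws are seeded separately).
#' @return object of class `human_model`, variant `"grm"`.
#' @export
human_model_grm <- function(n_items = 32L, n_factors = 4L, factor_cor = 0.3,
                            K = 5L, discrimination_range = c(1.0, 2.5),
                            location_sd = 0.9, threshold_sd = 1.5,
                            careless_prob = 0.1, max_severity = 0.6,
                            seed = 1L) {
  stopifnot(n_items >= 2, n_factors >= 1, n_items %% n_factors == 0, K >= 3)
  R <- if (is.matrix(factor_cor)) factor_cor else {
    m <- matrix(factor_cor, n_factors, n_factors); diag(m) <- 1; m
  }
  if (!is_symmetric(R) || any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("factor correlation matrix must be symmetric positive definite")
  old <- local_rng(seed); on.exit(restore_rng(old))
  a <- stats::runif(n_items, discrimination_range[1], discrimination_range[2])
  # K-1 strictly increasing thresholds per item, spread around a
  # per-item difficulty location (trait units)
  loc <- stats::rnorm(n_items, 0, location_sd)
  b <- t(vapply(seq_len(n_items),
                function(i) loc[i] + sort(stats::rnorm(K - 1L, 0, threshold_sd)),
                numeric(K - 1L)))
  item_factor <- rep(seq_len(n_factors), each = n_items / n_factors)
  structure(list(variant = "grm", n_items = n_items, n_factors = n_factors,
                 factor_cor = R, K = as.integer(K), discriminations = a,
                 thresholds = b, item_factor = item_factor,
                 careless_prob = careless_prob, max_severity = max_severity,
                 seed = seed),
            class = "human_model")
}

#' Resampling human model
#'
#' @param source a [response_matrix] of real (presumed human) rows to
#'   resample with replacement.
#' @return object of class `human_model`, variant `"resample"`.
#' @rdname human_model_grm
#' @export
human_model_resample <- function(source) {
  stopifnot(inherits(source, "response_matrix"))
  structure(list(variant = "resample", source = source,
                 K = source$categories[2] - source$categories[1] + 1L),
            class = "human_model")
}

#' Generate human response rows
#'
#' @param model a `human_model` (see [human_model_grm()]).
#' @param n number of rows.
#' @param seed integer seed (local to this call).
#' @return a [response_matrix].
#' @export
generate_humans <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "human_model"), n >= 1)
  if (!is.null(seed)) {
    old <- local_rng(seed); on.exit(restore_rng(old))
  }
  if (model$variant == "resample") {
    idx <- sample.int(nrow(model$source$values), n, replace = TRUE)
    return(rm_subset(model$source, idx))
  }
  # correlated latent traits via Cholesky
  L <- chol(model$factor_cor)
  theta <- matrix(stats::rnorm(n * model$n_factors), n) %*% L
  d <- model$n_items; K <- model$K
  # person-level careless severity: the proportion of a respondent's
  # items answered content-nonresponsively (uniformly at random).
  # Mostly zero, with a low-severity minority — the heterogeneity (and
  # heavy right tail in outlier statistics) real "presumed human"
  # web samples show.
  severity <- draw_severity(n, model)
  vals <- matrix(0L, n, d)
  u <- matrix(stats::runif(n * d), n, d)
  careless <- matrix(stats::runif(n * d), n, d) < severity
  for (j in seq_len(d)) {
    th <- theta[, model$item_factor[j]]
    # cumulative P(Z >= k) = plogis(a * (theta - b_{k-1})), k = 2..K;
    # category = 1 + #{k : u < P(Z >= k)} (difficulties in trait units)
    cum <- stats::plogis(model$discriminations[j] *
                           outer(th, model$thresholds[j, ], "-"))
    vals[, j] <- 1L + rowSums(u[, j] < cum)
  }
  if (any(careless))
    vals[careless] <- sample.int(K, sum(careless), replace = TRUE)
  response_matrix(vals, categories = c(1L, K))
}

## person-severity draw: a careless minority with severity uniform on
## (0, max_severity]; everyone else fully attentive (severity 0)
draw_severity <- function(n, model) {
  p <- model$careless_prob %||% 0.2
  mx <- model$max_severity %||% 0.6
  s <- numeric(n)
  careless <- stats::runif(n) < p
  s[careless] <- stats::runif(sum(careless), 0, mx)
  s
}

## save/restore the global RNG state around seeded generation so that
## generators are deterministic without disturbing the caller's stream
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Monte Carlo simulation design
#'
#' A fully crossed design over calibration human counts, target sizes,
#' contamination rates, bot models and classifiers. The published
#' study design is `4 x 2 x 5 x 2 x 2`: `n0tr` in {50, 100, 200, 400},
#' `n` in {500, 1000}, contamination in {.05, .25, .5, .75, .95}, bots
#' uniform or middle-preferring, classifier adaptive-mixture or
#' 99%-specificity Mahalanobis cutoff, 1000 replicates per cell.
#' Defaults instantiate that design; pass smaller sets and
#' `replicates` for desk-scale runs.
#'
#' @param n0tr_set calibration human sample sizes.
#' @param n_set target sample sizes.
#' @param contamination_set contamination rates in `[0, 1]`.
#' @param bot_set character vector of bot model names for the TARGET
#'   bots (calibration bots are always uniform).
#' @param classifier_set subset of `c("scump", "speccal")`.
#' @param replicates replicates per cell.
#' @param n1tr calibration bot count (default 2000).
#' @param base_seed base seed for per-cell stream derivation.
#' @return object of class `simulation_design` (a list of the above
#'   plus the expanded `cells` data.frame).
#' @export
simulation_design <- function(n0tr_set = c(50L, 100L, 200L, 400L),
                              n_set = c(500L, 1000L),
                              contamination_set = c(.05, .25, .5, .75, .95),
                              bot_set = c("uniform", "middle"),
                              classifier_set = c("scump", "speccal"),
                              replicates = 1000L, n1tr = 2000L,
                              base_seed = 1L) {
  stopifnot(length(n0tr_set) > 0, length(n_set) > 0,
            length(contamination_set) > 0, length(bot_set) > 0,
            length(classifier_set) > 0, replicates >= 1)
  stopifnot(all(classifier_set %in% c("scump", "speccal")))
  cells <- expand.grid(n0tr = n0tr_set, n = n_set,
                       contamination = contamination_set, bot = bot_set,
                       stringsAsFactors = FALSE)
  structure(list(n0tr_set = n0tr_set, n_set = n_set,
                 contamination_set = contamination_set, bot_set = bot_set,
                 classifier_set = classifier_set, replicates = replicates,
                 n1tr = n1tr, base_seed = base_seed, cells = cells),
            class = "simulation_design")
}

#' Run one simulation replicate
#'
#' One replicate of the study procedure: (1) generate the target with
#' exactly `n1 = round(n * contamination)` bot rows and `n0 = n - n1`
#' human rows (class counts fixed, not drawn from the mixture); (2)
#' generate the calibration sample with `n0tr` humans and `n1tr`
#' UNIFORM bots (the researcher's working assumption, regardless of the
#' true target bot model); (3) impute and convert everything to index
#' space against the calibration-human reference; (4) classify; (5)
#' score accuracy, specificity, sensitivity, flag rate and composite
#' AUC against ground truth.
#'
#' @param n target sample size.
#' @param contamination true bot proportion of the target.
#' @param n0tr calibration human count.
#' @param n1tr calibration bot count (default 2000).
#' @param human_model a `human_model`.
#' @param bot_model_target a [bot_model] for the TARGET bots.
#' @param classifiers character subset of `c("scump", "speccal",
#'   "oracle")`; all are evaluated on the same generated data.
#'   `"oracle"` predicts the true labels (harness sanity check).
#' @param indices index battery (default Mahalanobis + person-total).
#' @param settings per-index settings.
#' @param nominal_specificity for the `"speccal"` baseline (default .99).
#' @param seed integer seed for this replicate.
#' @return data.frame, one row per classifier: `classifier`,
#'   `accuracy`, `specificity`, `sensitivity`, `flag_rate`, `auc`,
#'   `lambda_hat` (NA for non-mixture classifiers).
#' @export
run_replicate <- function(n, contamination, n0tr, n1tr = 2000L,
                          human_model, bot_model_target,
                          classifiers = c("scump", "speccal"),
                          indices = c("mahalanobis", "person_total"),
                          settings = list(), nominal_specificity = 0.99,
                          seed = 1L) {
  stopifnot(all(classifiers %in% c("scump", "speccal", "oracle")))
  n1 <- as.integer(round(n * contamination)); n0 <- n - n1
  d <- if (human_model$variant == "grm") human_model$n_items
       else ncol(human_model$source$values)

  tgt_h <- if (n0 > 0) generate_humans(human_model, n0, seed = derive_seed(seed, "tgt-h"))
  tgt_b <- if (n1 > 0) generate_bots(bot_model_target, n1, d, seed = derive_seed(seed, "tgt-b"))
  target <- if (is.null(tgt_h)) tgt_b else if (is.null(tgt_b)) tgt_h else rm_bind(tgt_h, tgt_b)
  truth <- rep(0:1, c(n0, n1))

  cal_h <- generate_humans(human_model, n0tr, seed = derive_seed(seed, "cal-h"))
  cal_b <- generate_bots(bot_model("uniform", K = bot_model_target$K), n1tr, d,
                         seed = derive_seed(seed, "cal-b"))
  cal <- labeled_sample(rm_bind(cal_h, cal_b), rep(0:1, c(n0tr, n1tr)))

  cal_rm <- impute_middle(cal$responses)
  target_rm <- impute_middle(target)
  ref <- reference_from_calibration(cal)   # whole calibration sample
  cal_f <- featurize(cal_rm, ref, cal_rm, indices, settings)
  tgt_f <- featurize(target_rm, ref, cal_rm, indices, settings)

  one <- function(clf) {
    if (clf == "oracle") {
      rep_ <- confusion_metrics(truth, classification_report(truth, scores = as.numeric(truth), threshold = 0.5))
      lam <- NA_real_
    } else if (clf == "scump") {
      params <- estimate_class_params(cal_f, cal$labels,
                                      ridge = settings$ridge %||% 0)
      fit <- estimate_lambda(tgt_f, params)
      rep_ <- confusion_metrics(truth, bayes_classify(tgt_f, fit))
      lam <- fit$lambda_hat
    } else {
      rep_ <- confusion_metrics(truth,
        fit_predict_mahalanobis_cutoff(cal_f, cal$labels, tgt_f,
                                       nominal_specificity,
                                       ridge = settings$ridge %||% 0))
      lam <- NA_real_
    }
    m <- rep_$metrics
    data.frame(classifier = clf, accuracy = m$accuracy,
               specificity = m$specificity, sensitivity = m$sensitivity,
               flag_rate = m$flag_rate,
               auc = if (n0 > 0 && n1 > 0)
                 empirical_auc(rep_$scores, truth) else NA_real_,
               lambda_hat = lam, stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(classifiers, one))
}

#' Run a full Monte Carlo design
#'
#' Per-cell Monte Carlo means of all outcome measures, deterministic
#' given the design's base seed: each replicate of each cell gets its
#' own RNG stream derived by stable hashing of (base seed, cell
#' coordinates, replicate index), so cells are reproducible
#' independently and in any order.
#'
#' @param design a [simulation_design].
#' @param human_model a `human_model`.
#' @param indices,settings,nominal_specificity passed to
#'   [run_replicate()].
#' @param progress log per-cell progress to stderr.
#' @return data.frame: one row per (cell, classifier) with design
#'   coordinates, mean outcome measures, `mean_lambda_hat`, and
#'   `replicates`.
#' @export
run_design <- function(design, human_model,
                       indices = c("mahalanobis", "person_total"),
                       settings = list(), nominal_specificity = 0.99,
                       progress = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  out <- list()
  for (ci in seq_len(nrow(design$cells))) {
    cell <- design$cells[ci, ]
    bm <- bot_model(cell$bot)
    reps <- lapply(seq_len(design$replicates), function(r) {
      s <- derive_seed(design$base_seed, cell$n0tr, cell$n,
                       cell$contamination, cell$bot, r)
      run_replicate(cell$n, cell$contamination, cell$n0tr, design$n1tr,
                    human_model, bm, classifiers = design$classifier_set,
                    indices = indices, settings = settings,
                    nominal_specificity = nominal_specificity, seed = s)
    })
    reps <- do.call(rbind, reps)
    agg <- do.call(rbind, lapply(split(reps, reps$classifier), function(g)
      data.frame(n0tr = cell$n0tr, n = cell$n,
                 contamination = cell$contamination, bot = cell$bot,
                 classifier = g$classifier[1],
                 accuracy = mean(g$accuracy),
                 specificity = mean(g$specificity, na.rm = TRUE),
                 sensitivity = mean(g$sensitivity, na.rm = TRUE),
                 flag_rate = mean(g$flag_rate),
                 auc = mean(g$auc, na.rm = TRUE),
                 mean_lambda_hat = mean(g$lambda_hat),
                 replicates = design$replicates,
                 stringsAsFactors = FALSE)))
    out[[ci]] <- agg
    if (progress)
      scump_log(sprintf("cell %d/%d done (n0tr=%d, n=%d, lambda=%.2f, bots=%s)",
                        ci, nrow(design$cells), cell$n0tr, cell$n,
                        cell$contamination, cell$bot))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
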