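test_that("class parameter estimates are the per-class MLEs", {
  fm <- feature_matrix(rbind(c(0, 0), c(2, 2), c(5, 1), c(7, 3)),
                       index_names = c("u", "v"))
  # two rows per class: the MLEs are returned even though the
  # covariances are singular (density evaluation errors later)
  p <- suppressMessages(estimate_class_params(fm, c(0, 0, 1, 1)))
  expect_equal(unname(p$mean0), c(1, 1))
  expect_equal(unname(p$cov0), matrix(1, 2, 2))   # divisor 2, not 1
  expect_equal(unname(p$mean1), c(6, 2))

  expect_error(estimate_class_params(fm, c(0, 0, 0, 0)), "class 1 absent|fewer")

  # brute-force oracle on a 50x4 fixture
  set.seed(13)
  X <- matrix(rnorm(200), 50, 4)
  lab <- rep(0:1, 25)
  p2 <- estimate_class_params(feature_matrix(X), lab)
  rows <- X[lab == 1, ]
  mu <- colSums(rows) / nrow(rows)
  S <- matrix(0, 4, 4)
  for (i in seq_len(nrow(rows)))
    S <- S + tcrossprod(rows[i, ] - mu) / nrow(rows)
  expect_equal(unname(p2$mean1), unname(mu))
  expect_equal(unname(p2$cov1), unname(S))
})

test_that("the mixture score matches hand-derived values", {
  # identical class densities: flat likelihood, zero score everywhere
  d <- c(0.2, 0.5, 1.3)
  for (l in c(0, 0.3, 1))
    expect_equal(mixture_score(l, d, d, log = FALSE), 0)
  # single observation with phi1 = 2 phi0: positive for all lambda
  for (l in c(0, 0.5, 1))
    expect_gt(mixture_score(l, 2, 1, log = FALSE), 0)
  # ratios {3, 1/3}: score crosses zero exactly at lambda = 1/2
  expect_equal(mixture_score(0.5, c(3, 1/3), c(1, 1), log = FALSE), 0)
  expect_gt(mixture_score(0.25, c(3, 1/3), c(1, 1), log = FALSE), 0)
  expect_lt(mixture_score(0.75, c(3, 1/3), c(1, 1), log = FALSE), 0)
  expect_error(mixture_score(0.5, c(0, 1), c(0, 1), log = FALSE), "zero density")
})

test_that("the contamination estimator honors the endpoint rule", {
  p <- params1d(mu1 = 1)
  # every row more likely under the bot class -> endpoint 1
  fit1 <- estimate_lambda(feature_matrix(cbind(f = points_for_ratios(c(4, 2, 1.5)))), p)
  expect_equal(fit1$lambda_hat, 1)
  expect_true(fit1$endpoint)
  # ratios {2, 0.5, 0.1}: score at 0 is (1 - 0.5 - 0.9) < 0 -> endpoint 0
  fit0 <- estimate_lambda(feature_matrix(cbind(f = points_for_ratios(c(2, 0.5, 0.1)))), p)
  expect_equal(fit0$lambda_hat, 0)
  expect_true(fit0$endpoint)
  # ratios {3, 1/3} -> interior root at exactly 1/2
  fit5 <- estimate_lambda(feature_matrix(cbind(f = points_for_ratios(c(3, 1/3)))), p)
  expect_false(fit5$endpoint)
  expect_equal(fit5$lambda_hat, 0.5, tolerance = 1e-7)
})

test_that("lambda-hat matches a dense grid argmax and the likelihood is concave", {
  p <- params1d(mu1 = 1.5)
  grid <- seq(0, 1, length.out = 2001)
  for (s in 1:6) {
    set.seed(s)
    lam <- runif(1, 0.1, 0.9)
    x <- c(rnorm(round(200 * (1 - lam))), rnorm(round(200 * lam), 1.5))
    fm <- feature_matrix(cbind(f = x))
    fit <- estimate_lambda(fm, p, tol = 1e-10)
    ll <- grid_loglik(grid, fit$log1, fit$log0)
    expect_lte(max(ll) - fit$loglik_at_max, 1e-6)
    expect_equal(fit$lambda_hat, grid[which.max(ll)], tolerance = 1e-3)
    # maximum dominates both endpoints
    expect_gte(fit$loglik_at_max + 1e-9, ll[1])
    expect_gte(fit$loglik_at_max + 1e-9, ll[length(ll)])
    # numerical concavity of the log-likelihood
    expect_true(all(diff(diff(ll)) < 1e-7))
  }
})

test_that("label swap maps lambda-hat to its complement", {
  set.seed(33)
  x <- c(rnorm(120), rnorm(80, 1.5))
  fm <- feature_matrix(cbind(f = x))
  p <- params1d(mu1 = 1.5)
  pswap <- p
  pswap$mean0 <- p$mean1; pswap$cov0 <- p$cov1; pswap$n0 <- p$n1
  pswap$mean1 <- p$mean0; pswap$cov1 <- p$cov0; pswap$n1 <- p$n0
  f1 <- estimate_lambda(fm, p, tol = 1e-10)
  f2 <- estimate_lambda(fm, pswap, tol = 1e-10)
  expect_equal(f2$lambda_hat, 1 - f1$lambda_hat, tolerance = 1e-7)
})

test_that("lambda is recovered in an ideal two-Gaussian world", {
  # classes N(0, I) vs N(2.5 * 1, I), J = 2, n = 10,000
  set.seed(77)
  Xc <- rbind(matrix(rnorm(4000 * 2), ncol = 2),
              matrix(rnorm(4000 * 2, 2.5), ncol = 2))
  p <- estimate_class_params(feature_matrix(Xc), rep(0:1, each = 4000))
  for (lam in c(0.1, 0.5, 0.9)) {
    n1 <- round(10000 * lam)
    X <- rbind(matrix(rnorm((10000 - n1) * 2), ncol = 2),
               matrix(rnorm(n1 * 2, 2.5), ncol = 2))
    fit <- estimate_lambda(feature_matrix(X), p)
    expect_lt(abs(fit$lambda_hat - lam), 0.03)
  }
})

test_that("Bayes classification follows the posterior with spared ties", {
  p <- params1d(mu1 = 1)
  fm <- feature_matrix(cbind(f = points_for_ratios(c(5, 0.1, 1.2, 0.9))))
  # degenerate prior lambda = 0: everyone spared
  fit0 <- estimate_lambda(feature_matrix(cbind(f = points_for_ratios(c(0.5, 0.2)))), p)
  rep0 <- bayes_classify(feature_matrix(cbind(f = points_for_ratios(c(5, 0.1)))), fit0)
  expect_equal(fit0$lambda_hat, 0)
  expect_equal(rep0$predicted, c(0L, 0L))

  # exact tie is spared: lambda = 1/2 and ratio exactly 1
  fit5 <- estimate_lambda(feature_matrix(cbind(f = points_for_ratios(c(3, 1/3)))), p)
  fit5$lambda_hat <- 0.5   # make the tie exact, not bisection-approximate
  tie <- bayes_classify(feature_matrix(cbind(f = points_for_ratios(1))), fit5)
  expect_equal(tie$predicted, 0L)

  # prediction equals thresholding the printed composite at tau = 0
  set.seed(41)
  x <- rnorm(300, 0.6)
  fm2 <- feature_matrix(cbind(f = x))
  fit <- estimate_lambda(fm2, p)
  rep_ <- bayes_classify(fm2, fit)
  composite <- fit$lambda_hat * exp(fit$log1) - (1 - fit$lambda_hat) * exp(fit$log0)
  expect_equal(rep_$predicted, as.integer(composite > 0))
  # decisions invariant to common positive rescaling of both densities
  fit_sc <- fit
  fit_sc$log1 <- fit$log1 + 123.4
  fit_sc$log0 <- fit$log0 + 123.4
  expect_equal(bayes_classify(fit = fit_sc)$predicted, rep_$predicted)
})

test_that("the pipeline adapts lambda-hat to the target composition", {
  cal <- make_cal(nh = 120, nb = 500, seed = 2)
  hm <- human_model_grm(seed = 1)
  # uncontaminated target: the calibration humans themselves
  res_h <- scump(cal, rm_subset(cal$responses, cal$labels == 0L))
  expect_lt(res_h$fit$lambda_hat, 0.1)
  expect_lt(mean(res_h$report$predicted), 0.1)
  # saturated target of calibration-style bots
  bots <- generate_bots(bot_model("uniform"), 300, d = 32, seed = 9)
  res_b <- scump(cal, bots)
  expect_gt(res_b$fit$lambda_hat, 0.9)
  expect_gt(mean(res_b$report$predicted), 0.9)
})

test_that("fitted models round-trip through JSON", {
  cal <- make_cal(nh = 60, nb = 200, seed = 4)
  res <- scump(cal, rm_subset(cal$responses, cal$labels == 0L))
  path <- withr::local_tempfile(fileext = ".json")
  write_scump_model(res$fit$params, path, fit = res$fit,
                    settings = list(indices = c("mahalanobis", "person_total")))
  p2 <- read_scump_model(path)
  expect_equal(unname(p2$mean0), unname(res$fit$params$mean0), tolerance = 1e-12)
  expect_equal(unname(p2$cov1), unname(res$fit$params$cov1), tolerance = 1e-12)
  expect_equal(attr(p2, "model_meta")$lambda_hat, res$fit$lambda_hat)
})
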