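test_that("reference statistics match brute-force column means/covariances", {
  # humans {(1,1),(3,3)} -> mean (2,2)
  cal <- labeled_sample(response_matrix(matrix(c(1L,3L,2L,4L, 1L,3L,5L,1L), ncol = 2)),
                        c(0, 0, 1, 1))
  ref <- reference_from_humans(cal)
  expect_equal(unname(ref$mean), c(2, 2))
  expect_equal(ref$source_n, 2L)

  # fewer than 2 humans is rejected at construction
  expect_error(labeled_sample(make_rm(4, 3), c(1, 1, 1, 1)), "human")

  # brute-force oracle on a 5x3 random fixture (divisor n)
  rm <- make_rm(5, 3, seed = 7)
  cal <- labeled_sample(rm_stack(rm, make_rm(2, 3, seed = 8)),
                        c(rep(0, 5), 1, 1))
  ref <- reference_from_humans(cal)
  expect_equal(unname(ref$mean), unname(colMeans(rm$values)))
  n <- 5
  S <- matrix(0, 3, 3)
  for (i in 1:n) {
    dlt <- rm$values[i, ] - colMeans(rm$values)
    S <- S + tcrossprod(dlt) / n
  }
  expect_equal(unname(ref$covariance), unname(S))

  # full-calibration reference covers every row
  refc <- reference_from_calibration(cal)
  expect_equal(refc$source_n, 7L)
  expect_equal(unname(refc$mean), unname(colMeans(cal$responses$values)))
})

test_that("squared Mahalanobis distance matches closed forms", {
  ref <- structure(list(mean = c(1, 2), covariance = diag(2), source_n = 10),
                   class = "reference_stats")
  expect_equal(mahalanobis_distance(c(1, 2), ref), 0)
  expect_equal(mahalanobis_distance(c(2, 3), ref), 2)    # (1,1), identity S
  ref$covariance <- diag(c(2, 2))
  expect_equal(mahalanobis_distance(c(3, 2), ref), 2)    # (2,0), S = diag(2,2)
  # matches stats::mahalanobis (squared form) on a random instance
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  ref2 <- structure(list(mean = colMeans(X), covariance = cov(X), source_n = 10),
                    class = "reference_stats")
  expect_equal(mahalanobis_distance(X, ref2),
               unname(stats::mahalanobis(X, colMeans(X), cov(X))))
})

test_that("Mahalanobis is invariant under invertible affine maps", {
  set.seed(11)
  for (rep in 1:5) {
    z <- rnorm(4); m <- rnorm(4)
    A0 <- matrix(rnorm(16), 4); S <- crossprod(A0) + diag(4)
    ref <- structure(list(mean = m, covariance = S, source_n = 99),
                     class = "reference_stats")
    B <- matrix(rnorm(16), 4); b <- rnorm(4)
    refT <- structure(list(mean = as.numeric(B %*% m + b),
                           covariance = B %*% S %*% t(B), source_n = 99),
                      class = "reference_stats")
    expect_equal(mahalanobis_distance(as.numeric(B %*% z + b), refT),
                 mahalanobis_distance(z, ref), tolerance = 1e-8)
  }
})

test_that("singular reference covariance errors unless a ridge is given", {
  vals <- cbind(rep(3L, 6), sample.int(5, 6, TRUE), sample.int(5, 6, TRUE))
  cal <- labeled_sample(response_matrix(vals), c(0, 0, 0, 0, 1, 1))
  ref <- reference_from_humans(cal)
  expect_error(mahalanobis_distance(c(3, 2, 2), ref), "singular")
  expect_gte(mahalanobis_distance(c(3, 2, 2), ref, ridge = 1e-8), 0)
})

test_that("person-total correlation tracks the reference mean profile", {
  ref <- structure(list(mean = c(1, 2, 4, 5), covariance = diag(4), source_n = 9),
                   class = "reference_stats")
  expect_equal(as.numeric(person_total_cor(c(1, 2, 4, 5), ref)), 1)
  # reversed pattern z = (K+1) - m
  expect_equal(as.numeric(person_total_cor(6 - c(1, 2, 4, 5), ref)), -1)
  # constant rows carry no correlation information: 0 plus a flag
  r <- suppressMessages(person_total_cor(c(3, 3, 3, 3), ref))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  # invariant to positive affine rescaling; antisymmetric under reflection
  z <- c(2, 1, 5, 4)
  expect_equal(as.numeric(person_total_cor(2.5 * z + 1, ref)),
               as.numeric(person_total_cor(z, ref)))
  expect_equal(as.numeric(person_total_cor(6 - z, ref)),
               -as.numeric(person_total_cor(z, ref)))
})

test_that("featurize composes registered indices in request order", {
  ref <- structure(list(mean = c(1, 2, 4, 5), covariance = diag(4), source_n = 9),
                   class = "reference_stats")
  rm <- response_matrix(matrix(c(1L, 2L, 4L, 5L), nrow = 1, ncol = 4))
  fm <- featurize(rm, ref)
  expect_equal(unname(fm$values[1, ]), c(0, 1))  # at the mean: D = 0, r = 1
  expect_equal(fm$index_names, c("mahalanobis", "person_total"))
  expect_equal(fm$orientations, c("increasing", "decreasing"))
  fm2 <- featurize(rm, ref, indices = c("person_total", "mahalanobis"))
  expect_equal(fm2$index_names, c("person_total", "mahalanobis"))
  expect_error(featurize(rm, ref, indices = "no_such_index"), "unknown index")

  # column equals a per-row oracle loop on a 10x32 fixture
  big <- make_rm(10, 32, seed = 5)
  refb <- reference_from_calibration(
    labeled_sample(make_rm(60, 32, seed = 6), rep(0:1, each = 30)))
  fmb <- featurize(big, refb)
  oracle <- vapply(seq_len(10), function(i)
    mahalanobis_distance(big$values[i, ], refb), numeric(1))
  expect_equal(unname(fmb$values[, 1]), oracle)
})

test_that("in-sample squared Mahalanobis averages to the item count", {
  # property of the MLE covariance: mean in-sample D equals d exactly
  rm <- make_rm(220, 8, seed = 9)
  cal <- labeled_sample(rm_stack(rm, make_rm(5, 8, seed = 10)),
                        rep(0:1, c(220, 5)))
  ref <- reference_from_humans(cal)
  m <- mean(mahalanobis_distance(rm$values, ref))
  expect_gte(m, 0.8 * 8)
  expect_lte(m, 1.2 * 8)
})

test_that("suspicion recode negates decreasing columns and preserves AUC", {
  set.seed(21)
  fm <- feature_matrix(cbind(a = rnorm(40), b = rnorm(40)),
                       orientations = c("increasing", "decreasing"))
  inc <- to_suspicion_increasing(fm)
  expect_equal(inc$values[, "a"], fm$values[, "a"])
  expect_equal(inc$values[, "b"], -fm$values[, "b"])
  expect_true(all(inc$orientations == "increasing"))
  # empirical AUC identical after flipping direction
  truth <- rep(0:1, each = 20)
  expect_equal(empirical_auc(inc$values[, "b"], truth),
               1 - empirical_auc(fm$values[, "b"], truth))
})

test_that("factor-based indices honor their ranges and determinism", {
  refrm <- impute_middle(generate_humans(human_model_grm(seed = 2), 150, seed = 3))
  z <- make_rm(6, 32, seed = 4)$values
  res <- fmt_index(z, refrm, n_dimensions = 4, n_iterations = 30)
  expect_true(all(res$coherence >= 0 & res$coherence <= 1))
  expect_true(all(res$reliability >= -1 & res$reliability <= 1))
  res2 <- fmt_index(z, refrm, n_dimensions = 4, n_iterations = 30)
  expect_identical(res, res2)                     # deterministic
  expect_error(fmt_index(z, refrm, n_dimensions = 32), "n_dimensions")
  # registered as suspicion-decreasing plugins
  ref <- scump:::reference_stats(refrm$values)
  fm <- featurize(response_matrix(z), ref, refrm,
                  indices = c("fmt_coherence", "fmt_reliability"))
  expect_true(all(fm$orientations == "decreasing"))
})
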