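test_that("bot models carry the stated probability mass functions", {
  mid <- bot_model("middle")
  expect_equal(mid$pmf, c(0.1, 0.2, 0.4, 0.2, 0.1))
  expect_equal(bot_model("uniform", K = 5)$pmf, rep(0.2, 5))
  expect_error(bot_model("custom", pmf = c(0.5, 0.5, 0.5)), "length|sum")
  expect_error(bot_model("custom", K = 2, pmf = c(0.7, 0.2)), "sum")

  # uniform draws: each category frequency within 5 sigma of 1/K
  rm <- generate_bots(bot_model("uniform"), n = 2000, d = 50, seed = 3)
  freq <- tabulate(rm$values, 5) / 1e5
  sigma <- sqrt(0.2 * 0.8 / 1e5)
  expect_true(all(abs(freq - 0.2) < 5 * sigma))

  # seeded determinism
  expect_identical(generate_bots(bot_model("middle"), 20, 8, seed = 4)$values,
                   generate_bots(bot_model("middle"), 20, 8, seed = 4)$values)
})

test_that("the graded-response generator produces structured humans", {
  hm <- human_model_grm(seed = 2)
  expect_equal(dim(hm$thresholds), c(32L, 4L))
  expect_true(all(apply(hm$thresholds, 1, function(x) all(diff(x) > 0))))

  rm <- generate_humans(hm, 2000, seed = 5)
  expect_true(all(rm$values >= 1 & rm$values <= 5))
  # within-factor items correlate more than between-factor items
  R <- cor(rm$values)
  same <- outer(hm$item_factor, hm$item_factor, "==") & upper.tri(R)
  diff_ <- !outer(hm$item_factor, hm$item_factor, "==") & upper.tri(R)
  expect_gt(mean(R[same]), mean(R[diff_]))

  # zero discriminations: no latent information, symmetric marginals
  hm0 <- human_model_grm(seed = 2, careless_prob = 0)
  hm0$discriminations[] <- 0
  rm0 <- generate_humans(hm0, 3000, seed = 6)
  expect_equal(mean(rm0$values == 1), mean(rm0$values == 5), tolerance = 0.05)

  # resampling draws members of the source
  src <- make_rm(3, 6, seed = 7)
  res <- generate_humans(human_model_resample(src), 10, seed = 8)
  keys <- apply(src$values, 1, paste, collapse = ",")
  expect_true(all(apply(res$values, 1, paste, collapse = ",") %in% keys))

  # invalid factor structure is rejected
  expect_error(human_model_grm(n_items = 10, n_factors = 4), "n_items")
  expect_error(human_model_grm(factor_cor = matrix(c(1, 2, 2, 1), 2),
                               n_factors = 2, n_items = 32), "positive definite")
})

test_that("replicates are reproducible and internally consistent", {
  hm <- human_model_grm(seed = 1)
  r1 <- run_replicate(100, 0.4, 60, 300, hm, bot_model("uniform"),
                      classifiers = c("oracle", "scump"), seed = 11)
  r2 <- run_replicate(100, 0.4, 60, 300, hm, bot_model("uniform"),
                      classifiers = c("oracle", "scump"), seed = 11)
  expect_identical(r1, r2)                      # bitwise reproducible
  expect_equal(r1$accuracy[r1$classifier == "oracle"], 1)  # harness sanity
  # fixed class counts: accuracy is exactly the weighted mean identity
  sc <- r1[r1$classifier == "scump", ]
  expect_equal(sc$accuracy,
               0.4 * sc$sensitivity + 0.6 * sc$specificity)
})

test_that("design cells aggregate their own replicates", {
  hm <- human_model_grm(seed = 1)
  des <- simulation_design(n0tr_set = 60, n_set = 80, contamination_set = 0.5,
                           bot_set = "uniform", classifier_set = "scump",
                           replicates = 3, n1tr = 300, base_seed = 9)
  res <- run_design(des, hm)
  expect_equal(nrow(res), 1L)
  # recompute the three replicates independently
  reps <- vapply(1:3, function(r) {
    s <- derive_seed(9, 60L, 80L, 0.5, "uniform", r)
    run_replicate(80, 0.5, 60, 300, hm, bot_model("uniform"),
                  classifiers = "scump", seed = s)$accuracy
  }, numeric(1))
  expect_equal(res$accuracy, mean(reps))
  # a 1-cell, 1-replicate design reduces to run_replicate
  des1 <- simulation_design(n0tr_set = 60, n_set = 80, contamination_set = 0.5,
                            bot_set = "uniform", classifier_set = "scump",
                            replicates = 1, n1tr = 300, base_seed = 9)
  res1 <- run_design(des1, hm)
  one <- run_replicate(80, 0.5, 60, 300, hm, bot_model("uniform"),
                       classifiers = "scump",
                       seed = derive_seed(9, 60L, 80L, 0.5, "uniform", 1))
  expect_equal(res1$accuracy, one$accuracy)

  # the published full design instantiates as 4 x 2 x 5 x 2 x 2 = 160 cells
  full <- simulation_design()
  expect_equal(nrow(full$cells) * length(full$classifier_set), 160L)
  expect_equal(full$replicates, 1000L)
  expect_equal(full$n1tr, 2000L)
})

test_that("derived seeds are stable, distinct, and 31-bit", {
  s1 <- derive_seed(1, "a", 2, 0.5)
  expect_identical(s1, derive_seed(1, "a", 2, 0.5))
  expect_false(s1 == derive_seed(1, "a", 2, 0.75))
  expect_false(s1 == derive_seed(2, "a", 2, 0.5))
  many <- vapply(1:500, function(i) derive_seed(7, "cell", i), numeric(1))
  expect_true(all(many >= 0 & many < 2^31))
  expect_gt(length(unique(many)), 495)
})
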