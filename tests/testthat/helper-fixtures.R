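# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except the packaged extdata CSVs where a test is
# specifically about file I/O.

# small labeled calibration sample: nh humans on a fixed grm world plus
# nb uniform bots
make_cal <- function(nh = 100, nb = 400, seed = 1, model_seed = 1) {
  hm <- human_model_grm(seed = model_seed)
  hum <- generate_humans(hm, nh, seed = derive_seed(seed, "h"))
  bot <- generate_bots(bot_model("uniform"), nb, d = hm$n_items,
                       seed = derive_seed(seed, "b"))
  labeled_sample(rm_stack(hum, bot), rep(0:1, c(nh, nb)))
}

# deterministic small response matrix with values in 1..5
make_rm <- function(n, d, seed = 1) {
  set.seed(seed)
  response_matrix(matrix(sample.int(5, n * d, replace = TRUE), n, d))
}

# 1-D Gaussian class parameters with unit sds: density ratio at x is
# exp(mu1 * x - mu1^2 / 2), handy for crafting exact ratio fixtures
params1d <- function(mu1 = 1) {
  fm <- feature_matrix(cbind(f = c(-1, 1, -1 + mu1, 1 + mu1)))
  estimate_class_params(fm, c(0, 0, 1, 1))
}

# feature points whose density ratios under params1d(mu1) equal `r`
points_for_ratios <- function(r, mu1 = 1) (log(r) + mu1^2 / 2) / mu1

# mixture log-likelihood on a lambda grid from class log-densities
# (independent of the package's internal evaluation path)
grid_loglik <- function(lambda, log1, log0) {
  vapply(lambda, function(l) {
    if (l == 0) return(sum(log0))
    if (l == 1) return(sum(log1))
    a <- log(l) + log1; b <- log(1 - l) + log0
    m <- pmax(a, b)
    sum(m + log1p(exp(pmin(a, b) - m)))
  }, numeric(1))
}
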