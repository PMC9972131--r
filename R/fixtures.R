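#' Write the packaged demonstration fixtures
#'
#' Writes two small seeded CSV data sets — 100 synthetic
#' graded-response-model humans and 100 uniform bots, 32 items on a
#' 5-point scale — byte-identical across runs for a given seed. These
#' are the files shipped under `inst/extdata/` and used by the tests
#' and the README example.
#'
#' @param dir output directory (created if absent).
#' @param seed integer seed (default 20220730).
#' @param n_humans,n_bots row counts (default 100 each).
#' @return named character vector of the two file paths, invisibly.
#' @export
make_fixtures <- function(dir = ".", seed = 20220730L,
                          n_humans = 100L, n_bots = 100L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hm <- human_model_grm(seed = derive_seed(seed, "model"))
  humans <- generate_humans(hm, n_humans, seed = derive_seed(seed, "humans"))
  bots <- generate_bots(bot_model("uniform"), n_bots, d = hm$n_items,
                        seed = derive_seed(seed, "bots"))
  paths <- c(humans = file.path(dir, "synthetic_humans.csv"),
             bots = file.path(dir, "uniform_bots.csv"))
  write_response_matrix(humans, paths["humans"])
  write_response_matrix(bots, paths["bots"])
  invisible(paths)
}

#' Path to a packaged fixture file
#'
#' @param name `"synthetic_humans.csv"` or `"uniform_bots.csv"`.
#' @return file path inside the installed package.
#' @export
scump_extdata <- function(name) {
  p <- system.file("extdata", name, package = "scump")
  if (p == "") stop("no such packaged fixture: ", name)
  p
}
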