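#' Hypothetical two-normal nonresponsivity index
#'
#' Closed-form theory for a single suspicion-increasing index whose two
#' classes are normal: humans `N(mu0, sd0^2)` and bots `N(mu1, sd1^2)`,
#' mixed with contamination rate `lambda`. This small model makes the
#' specificity/accuracy trade-off exactly computable: every nominal
#' specificity implies a cutoff, hence a sensitivity, hence (via the
#' weighted-mean identity) an accuracy at each contamination rate.
#'
#' @param mu0,sd0 human mean and sd (defaults 0, 1).
#' @param mu1,sd1 bot mean and sd (defaults from
#'   [two_normal_reference()]).
#' @param lambda contamination rate in `[0, 1]` (default 0.5).
#' @return object of class `two_normal_nri`.
#' @export
two_normal_nri <- function(mu0 = 0, sd0 = 1, mu1 = NULL, sd1 = NULL,
                           lambda = 0.5) {
  ref <- two_normal_reference()
  mu1 <- mu1 %||% ref$mu1
  sd1 <- sd1 %||% ref$sd1
  stopifnot(sd0 > 0, sd1 > 0, lambda >= 0, lambda <= 1)
  structure(list(mu0 = mu0, sd0 = sd0, mu1 = mu1, sd1 = sd1,
                 lambda = lambda), class = "two_normal_nri")
}

#' Reference constants for the illustrative two-normal model
#'
#' The published illustration standardizes humans to `N(0, 1)` but does
#' not print the bot parameters; they were back-solved by the packaged
#' grid-search oracle (`tools/solve_two_normal.R`), which minimizes the
#' maximum deviation across the 20 printed accuracy cells and the
#' printed AUC. The solver converges to bot mean 2.5, bot sd 1.
#'
#' @return list with `mu1 = 2.5`, `sd1 = 1`.
#' @export
two_normal_reference <- function() list(mu1 = 2.5, sd1 = 1)

#' Operating point of a specificity cutoff under the two-normal model
#'
#' The cutoff attaining a given specificity on the human normal is
#' `mu0 + sd0 * qnorm(specificity)`; its sensitivity is the bot mass
#' above the cutoff; its accuracy follows from [weighted_accuracy()]
#' with the model's contamination rate.
#'
#' @param model a [two_normal_nri].
#' @param specificity nominal specificity in `(0, 1)`.
#' @return list with `cutoff`, `sensitivity`, `accuracy`.
#' @export
two_normal_operating_point <- function(model, specificity) {
  stopifnot(inherits(model, "two_normal_nri"),
            specificity > 0, specificity < 1)
  cutoff <- model$mu0 + model$sd0 * stats::qnorm(specificity)
  sensitivity <- 1 - stats::pnorm((cutoff - model$mu1) / model$sd1)
  list(cutoff = cutoff, sensitivity = sensitivity,
       accuracy = weighted_accuracy(model$lambda, sensitivity, specificity))
}

#' Closed-form AUC of the two-normal model
#'
#' `AUC = Phi((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`: the probability that
#' a bot draw exceeds a human draw.
#'
#' @param model a [two_normal_nri].
#' @return AUC in `[0, 1]`.
#' @export
two_normal_auc <- function(model) {
  stopifnot(inherits(model, "two_normal_nri"))
  stats::pnorm((model$mu1 - model$mu0) / sqrt(model$sd0^2 + model$sd1^2))
}

#' Accuracy-maximizing cutoff of the two-normal mixture
#'
#' The most accurate cutoff sits where the prevalence-weighted class
#' densities cross: it solves `lambda * f1(c) = (1 - lambda) * f0(c)`.
#' For equal sds the log-density equation is linear and has the closed
#' form below; for unequal sds it is quadratic and the crossing on the
#' between-means branch is returned.
#'
#' @param model a [two_normal_nri] with `lambda` strictly inside (0, 1).
#' @return the cutoff (scalar).
#' @export
two_normal_optimal_cutoff <- function(model) {
  stopifnot(inherits(model, "two_normal_nri"))
  lam <- model$lambda
  if (lam <= 0 || lam >= 1)
    stop("the weighted-density crossing needs lambda strictly inside (0, 1)")
  w <- log(lam / (1 - lam))
  if (isTRUE(all.equal(model$sd0, model$sd1))) {
    s2 <- model$sd0^2
    # linear log-density equation
    return((model$mu0 + model$mu1) / 2 - s2 * w / (model$mu1 - model$mu0))
  }
  # quadratic: a c^2 + b c + cc = 0 from equating weighted log-densities
  a <- 1 / model$sd1^2 - 1 / model$sd0^2
  b <- 2 * (model$mu0 / model$sd0^2 - model$mu1 / model$sd1^2)
  cc <- model$mu1^2 / model$sd1^2 - model$mu0^2 / model$sd0^2 +
    2 * (log(model$sd1 / model$sd0) - w)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) stop("no weighted-density crossing for this configuration")
  roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  between <- roots[roots >= min(model$mu0, model$mu1) &
                   roots <= max(model$mu0, model$mu1)]
  if (length(between)) between[1] else roots[which.min(abs(roots - (model$mu0 + model$mu1) / 2))]
}

#' Reproduce the closed-form accuracy table
#'
#' Accuracy (in percent, one decimal, round-half-even) of specificity
#' cutoffs 85/90/95/99% at contamination rates 5/25/50/75/95% under the
#' reference two-normal model.
#'
#' @param contaminations contamination rates (rows).
#' @param specificities nominal specificities (columns).
#' @param percent if `TRUE` (default) format in percent to one decimal.
#' @return a numeric matrix, contaminations x specificities.
#' @export
two_normal_accuracy_table <- function(contaminations = c(.05, .25, .5, .75, .95),
                                      specificities = c(.85, .90, .95, .99),
                                      percent = TRUE) {
  out <- matrix(NA_real_, length(contaminations), length(specificities),
                dimnames = list(paste0(100 * contaminations, "%"),
                                paste0(100 * specificities, "%")))
  for (i in seq_along(contaminations))
    for (j in seq_along(specificities)) {
      m <- two_normal_nri(lambda = contaminations[i])
      acc <- two_normal_operating_point(m, specificities[j])$accuracy
      out[i, j] <- if (percent) round(100 * acc, 1) else acc
    }
  out
}
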