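#' Population scenario: stratum fractions and risks
#'
#' Describes a population divided into discrete risk strata by known risk
#' factors: the fraction of the population in each stratum and the disease
#' risk within it. Used for asymptotic power and relative-efficiency
#' calculations.
#'
#' @param risks Per-stratum population risks, each in (0,1).
#' @param fractions Per-stratum population fractions (default equal); must
#'   sum to 1.
#' @return An object of class `"population_scenario"`.
#' @examples
#' population_scenario(c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001))
#' @export
population_scenario <- function(risks, fractions = NULL) {
  if (any(!is.finite(risks)) || any(risks <= 0 | risks >= 1))
    stop("'risks' must lie strictly inside (0, 1)")
  k <- length(risks)
  if (is.null(fractions)) fractions <- rep(1 / k, k)
  if (length(fractions) != k || any(fractions <= 0))
    stop("'fractions' must be positive, one per stratum")
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("'fractions' must sum to 1")
  structure(list(risks = as.numeric(risks), fractions = as.numeric(fractions)),
            class = "population_scenario")
}

#' Read a population scenario from a JSON file
#'
#' Expects an object with fields `risks` and optionally `fractions`.
#' The two scenarios used for the bundled efficiency computations ship as
#' `system.file("extdata", "scenario1.json", package = "linkscore")` (seven
#' equal strata, risks 0.1 to 0.001) and `"scenario2.json"` (four equal
#' strata, risks 0.05 to 0.005).
#'
#' @param path Path to a JSON scenario file.
#' @return A `"population_scenario"`.
#' @export
read_scenario <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$risks)) stop("scenario JSON must contain a 'risks' field")
  population_scenario(obj$risks, obj$fractions)
}

#' @export
print.population_scenario <- function(x, ...) {
  cat("Population scenario with", length(x$risks), "strata\n")
  print(data.frame(fraction = x$fractions, risk = x$risks))
  invisible(x)
}

#' Case-control sampling design
#'
#' @param case_control_ratio Ratio of cases to controls in the study
#'   (default 1, i.e. equal numbers).
#' @param N Total sample size (needed for non-centrality parameters;
#'   efficiency ratios do not depend on it).
#' @return An object of class `"sampling_design"`.
#' @export
sampling_design <- function(case_control_ratio = 1, N = NULL) {
  if (case_control_ratio <= 0) stop("'case_control_ratio' must be positive")
  if (!is.null(N) && N <= 0) stop("'N' must be positive")
  structure(list(ratio = case_control_ratio, N = N,
                 case_fraction = case_control_ratio / (1 + case_control_ratio)),
            class = "sampling_design")
}

#' Study composition induced by case-control sampling
#'
#' Given stratum population fractions and risks, cases arise from stratum
#' \eqn{z} with probability \eqn{f_z \pi_z / \sum f \pi} and controls with
#' probability \eqn{f_z (1-\pi_z) / \sum f (1-\pi)}. Mixing these in the
#' design's case:control ratio gives each stratum's share \eqn{a_z} of the
#' study and its within-stratum case fraction \eqn{\mu_z}, which satisfies
#' the odds-shift relation to \eqn{\pi_z} with a sampling ratio common to all
#' strata.
#'
#' @param scenario A [population_scenario()].
#' @param design A [sampling_design()].
#' @return A data frame with columns `pi` (population risk), `a` (study
#'   share, summing to 1) and `mu` (study case fraction), one row per
#'   stratum.
#' @export
cc_composition <- function(scenario, design = sampling_design()) {
  f <- scenario$fractions; pi <- scenario$risks
  cfrac <- design$case_fraction
  p_case <- f * pi / sum(f * pi)
  p_ctrl <- f * (1 - pi) / sum(f * (1 - pi))
  a <- cfrac * p_case + (1 - cfrac) * p_ctrl
  mu <- cfrac * p_case / a
  data.frame(pi = pi, a = a, mu = mu)
}

#' Optimal stratum weights under an assumed true link
#'
#' The asymptotically efficient per-stratum weights are [link_weight()]
#' evaluated at the stratum population risks (unnormalized; tests and
#' efficiencies are invariant to a common rescaling).
#'
#' @inheritParams cc_composition
#' @param true_link The link assumed to hold in the population.
#' @return Numeric vector of weights, one per stratum.
#' @export
optimal_weights <- function(scenario, true_link) {
  link_weight(as_link(true_link), scenario$risks)
}

resolve_scenario_weights <- function(scenario, weights) {
  if (is.numeric(weights)) {
    if (length(weights) != length(scenario$risks))
      stop("numeric weights must have one entry per stratum")
    return(as.numeric(weights))
  }
  if (identical(weights, "unit")) return(rep(1, length(scenario$risks)))
  link_weight(as_link(weights), scenario$risks)
}

# Local-alternative non-centrality per unit N * beta^2 * Var(x).
#
# marginal: the weighted Cochran-Armitage statistic U = sum (x - xbar) w_z y.
# Its local mean has, besides the within-stratum term sum a w mu(1-mu) W*,
# a between-stratum term: case-control sampling makes E[x|z] shift by
# beta Var(x) W*(pi_z)(mu_z - pi_z), which covaries with E[w_z y | z] across
# strata. Its null variance is the whole-sample permutation variance
# Var(x) Var(w_z y). stratified: both margins are within-stratum, so the
# between term vanishes and the variance is sum a w^2 mu(1-mu).
ncp_core <- function(comp, w, wstar, test) {
  a <- comp$a; mu <- comp$mu; pi <- comp$pi
  info <- mu * (1 - mu)
  if (test == "stratified") {
    m <- sum(a * w * info * wstar)
    v <- sum(a * w^2 * info)
  } else {
    d <- mu - pi
    m <- sum(a * w * info * wstar) +
      sum(a * wstar * d * w * mu) - sum(a * wstar * d) * sum(a * w * mu)
    v <- sum(a * w^2 * mu) - sum(a * w * mu)^2
  }
  m^2 / v
}

#' Asymptotic relative efficiency of a weighted test under link misspecification
#'
#' Ratio of the non-centrality parameter of the chi-squared (1 df) weighted
#' test with the given analysis weights to its value with the optimal weights
#' for the true link, in the limit of a very small genotype effect. The
#' default `test = "marginal"` evaluates the weighted marginal
#' (Cochran-Armitage type) test, the test of practical interest when
#' genotype is independent of the stratifying factors; `"stratified"`
#' evaluates the weighted stratified test.
#'
#' @inheritParams cc_composition
#' @param true_link Link assumed to generate the data.
#' @param analysis_weights `"unit"`, a link (name or spec) whose weights at
#'   the stratum population risks are used, or a numeric per-stratum vector.
#' @param test `"marginal"` or `"stratified"`.
#' @return Efficiency in (0, 1]; 1 when the analysis weights are
#'   proportional to the optimal weights.
#' @examples
#' sc1 <- population_scenario(c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001))
#' efficiency(sc1, sampling_design(1), "probit", "unit")   # about 0.949
#' @export
efficiency <- function(scenario, design = sampling_design(), true_link,
                       analysis_weights, test = c("marginal", "stratified")) {
  test <- match.arg(test)
  comp <- cc_composition(scenario, design)
  wstar <- optimal_weights(scenario, true_link)
  w <- resolve_scenario_weights(scenario, analysis_weights)
  ncp_core(comp, w, wstar, test) / ncp_core(comp, wstar, wstar, test)
}

#' Non-centrality parameter of the weighted 1 df trend test
#'
#' Local-alternative non-centrality for a diallelic locus with additive 0/1/2
#' coding under Hardy-Weinberg equilibrium, effect `beta` per allele on the
#' true link's scale, assumed constant across strata.
#'
#' @inheritParams efficiency
#' @param beta Allelic effect on the true link scale.
#' @param maf Minor allele frequency (genotype variance `2 maf (1-maf)`).
#' @param N Total study size.
#' @return The non-centrality parameter (so mean chi-squared is about
#'   `1 + ncp`).
#' @export
ncp <- function(scenario, design = sampling_design(), true_link, beta,
                maf = 0.5, N, analysis_weights,
                test = c("marginal", "stratified")) {
  test <- match.arg(test)
  comp <- cc_composition(scenario, design)
  wstar <- optimal_weights(scenario, true_link)
  w <- resolve_scenario_weights(scenario, analysis_weights)
  var_x <- 2 * maf * (1 - maf)
  N * beta^2 * var_x * ncp_core(comp, w, wstar, test)
}

#' Efficiency curves over the power-odds family
#'
#' Two standard misspecification sweeps: with `panel = "true"`, data are
#' generated under the power-odds link at each grid exponent and analysed
#' with unit weights (the standard Cochran-Armitage test, i.e. analysis at
#' \eqn{\lambda = 0}); with `panel = "analysis"`, data follow the logistic
#' model and the analysis uses power-odds weights at each grid exponent.
#' Efficiency is 1 exactly at \eqn{\lambda = 0} in either sweep.
#'
#' @inheritParams efficiency
#' @param lambdas Grid of power-odds exponents.
#' @param panel `"true"`, `"analysis"`, or `"both"`.
#' @return A data frame with columns `panel`, `lambda`, `efficiency`.
#' @export
efficiency_curve <- function(scenario, design = sampling_design(),
                             lambdas = seq(-0.5, 1, by = 0.05),
                             panel = c("both", "true", "analysis"),
                             test = "marginal") {
  panel <- match.arg(panel)
  rows <- list()
  if (panel %in% c("both", "true"))
    rows$true <- data.frame(panel = "true", lambda = lambdas,
      efficiency = vapply(lambdas, function(l)
        efficiency(scenario, design, make_link("power_odds", l), "unit",
                   test = test), numeric(1)))
  if (panel %in% c("both", "analysis"))
    rows$analysis <- data.frame(panel = "analysis", lambda = lambdas,
      efficiency = vapply(lambdas, function(l)
        efficiency(scenario, design, "logit", make_link("power_odds", l),
                   test = test), numeric(1)))
  do.call(rbind, rows)
}
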