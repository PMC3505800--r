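#' Simulate a stratified case-control study
#'
#' Generates genotypes for a case-control sample drawn from a stratified
#' population in which disease risk follows a chosen link: within stratum
#' \eqn{z}, \eqn{g(\pi_z(x)) = \eta_z + \beta x} with the intercept solved so
#' that the risk at the mean genotype equals the stratum's nominal risk.
#' Genotypes are 0/1/2 under Hardy-Weinberg equilibrium, independent of
#' stratum in the population. Rather than rejection-sampling a cohort, the
#' exact case and control genotype frequencies are computed per stratum by
#' Bayes inversion of the risk model and then multinomially sampled to the
#' design's case and control counts, which makes small-effect studies cheap
#' enough for power work at many replicates.
#'
#' @param scenario A [population_scenario()].
#' @param true_link Link under which the data are generated.
#' @param beta Per-allele effect on the true link's scale.
#' @param maf Minor allele frequency.
#' @param design A [sampling_design()] (case:control ratio).
#' @param N Total sample size.
#' @param seed Seed; identical arguments and seed give identical data.
#' @return A [cc_data()] object.
#' @export
simulate_cc_study <- function(scenario, true_link, beta, maf = 0.5,
                              design = sampling_design(), N, seed = NULL) {
  link <- as_link(true_link)
  xs <- 0:2
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  f <- scenario$fractions; pi_z <- scenario$risks
  eta <- link$g(pi_z) - beta * 2 * maf
  r <- outer(eta, xs, function(e, x) link$g_inverse(e + beta * x))
  if (any(r <= 1e-12 | r >= 1 - 1e-12))
    stop("risk model leaves (0, 1) for an attainable genotype; ",
         "reduce 'beta' or change the link")
  pbar <- drop(r %*% hwe)
  n_case <- round(N * design$case_fraction)
  n_ctrl <- N - n_case
  pz_case <- f * pbar / sum(f * pbar)
  pz_ctrl <- f * (1 - pbar) / sum(f * (1 - pbar))
  k <- length(pi_z)
  with_seed(seed, {
    nz_case <- drop(stats::rmultinom(1, n_case, pz_case))
    nz_ctrl <- drop(stats::rmultinom(1, n_ctrl, pz_ctrl))
    y <- integer(0); x <- integer(0); z <- integer(0)
    for (j in seq_len(k)) {
      if (nz_case[j] > 0) {
        gx <- drop(stats::rmultinom(1, nz_case[j], hwe * r[j, ] / pbar[j]))
        y <- c(y, rep(1L, nz_case[j])); x <- c(x, rep(xs, gx)); z <- c(z, rep(j, nz_case[j]))
      }
      if (nz_ctrl[j] > 0) {
        gx <- drop(stats::rmultinom(1, nz_ctrl[j], hwe * (1 - r[j, ]) / (1 - pbar[j])))
        y <- c(y, rep(0L, nz_ctrl[j])); x <- c(x, rep(xs, gx)); z <- c(z, rep(j, nz_ctrl[j]))
      }
    }
    d <- cc_data(y, x, factor(z, levels = seq_len(k)))
    attr(d, "spec") <- list(true_link = link$name, lambda = link$lambda,
                            beta = beta, maf = maf, N = N, seed = seed)
    d
  })
}

#' Simulate sibling pairs under a prediction model
#'
#' Generic over the four risk models of this package. Log-link and
#' quadratic-log models draw bivariate normal genetic scores with
#' correlation 1/2 (risks above 1 are truncated to 1 and the truncated
#' fraction reported); the independent sufficient causes model draws shared
#' and unshared Poisson variant counts with means \eqn{\mu/2} each; the
#' probit model draws bivariate normal liabilities with correlation
#' \eqn{H/2}.
#'
#' @param model A `loglink_model`, `isc_model`, `probit_model` or
#'   `quadlog_model`.
#' @param n_pairs Number of sibling pairs.
#' @param seed Seed for reproducibility.
#' @return An object of class `"sib_sim"`: affection indicators `y1`, `y2`,
#'   empirical estimates `P_hat`, `lambda_s_hat` with delta-method standard
#'   errors, and `capped_fraction` where risks were truncated at 1.
#' @export
simulate_sib_pairs <- function(model, n_pairs, seed = NULL) {
  UseMethod("simulate_sib_pairs")
}

sib_sim_result <- function(y1, y2, capped_fraction = 0) {
  n <- length(y1)
  P_hat <- mean(c(y1, y2))
  p11 <- mean(y1 * y2)
  lambda_s_hat <- p11 / (mean(y1) * mean(y2))
  n_aff <- sum(y1)
  r_hat <- if (n_aff > 0) mean(y2[y1 == 1]) else NA_real_
  lambda_se <- if (n_aff > 0 && r_hat > 0)
    lambda_s_hat * sqrt((1 - r_hat) / (r_hat * n_aff) +
                          (1 - P_hat) / (P_hat * 2 * n)) else NA_real_
  structure(list(y1 = y1, y2 = y2, n_pairs = n,
                 P_hat = P_hat, P_se = sqrt(P_hat * (1 - P_hat) / (2 * n)),
                 lambda_s_hat = lambda_s_hat, lambda_s_se = lambda_se,
                 capped_fraction = capped_fraction),
            class = "sib_sim")
}

#' @export
print.sib_sim <- function(x, ...) {
  cat(sprintf("Sibling-pair simulation: %d pairs\n", x$n_pairs))
  cat(sprintf("  P_hat = %.4g (se %.2g), lambda_S_hat = %.3f (se %.2g)\n",
              x$P_hat, x$P_se, x$lambda_s_hat, x$lambda_s_se))
  if (x$capped_fraction > 0)
    cat(sprintf("  fraction of risks truncated at 1: %.3g\n", x$capped_fraction))
  invisible(x)
}

bvn_pair <- function(n, rho) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}

#' @export
simulate_sib_pairs.loglink_model <- function(model, n_pairs, seed = NULL) {
  with_seed(seed, {
    x <- bvn_pair(n_pairs, 0.5)
    risk <- exp(model$c0 + model$alpha * x)
    capped <- mean(risk >= 1)
    risk <- pmin(risk, 1)
    sib_sim_result(stats::rbinom(n_pairs, 1, risk[, 1]),
                   stats::rbinom(n_pairs, 1, risk[, 2]), capped)
  })
}

#' @export
simulate_sib_pairs.quadlog_model <- function(model, n_pairs, seed = NULL) {
  with_seed(seed, {
    x <- bvn_pair(n_pairs, 0.5)
    risk <- exp(model$c0 + model$c1 * x + model$c2 * x^2)
    capped <- mean(risk >= 1)
    risk <- pmin(risk, 1)
    sib_sim_result(stats::rbinom(n_pairs, 1, risk[, 1]),
                   stats::rbinom(n_pairs, 1, risk[, 2]), capped)
  })
}

#' @export
simulate_sib_pairs.isc_model <- function(model, n_pairs, seed = NULL) {
  with_seed(seed, {
    s <- stats::rpois(n_pairs, model$mu / 2)
    x1 <- s + stats::rpois(n_pairs, model$mu / 2)
    x2 <- s + stats::rpois(n_pairs, model$mu / 2)
    risk1 <- 1 - (1 - model$b) * (1 - model$p)^x1
    risk2 <- 1 - (1 - model$b) * (1 - model$p)^x2
    sib_sim_result(stats::rbinom(n_pairs, 1, risk1),
                   stats::rbinom(n_pairs, 1, risk2))
  })
}

#' @export
simulate_sib_pairs.probit_model <- function(model, n_pairs, seed = NULL) {
  with_seed(seed, {
    L <- bvn_pair(n_pairs, model$H / 2)
    sib_sim_result(as.integer(L[, 1] > model$T), as.integer(L[, 2] > model$T))
  })
}

#' Simulate independent subjects with genotype scores and outcomes
#'
#' Draws per-subject (score, affection) records from a prediction model, for
#' empirical ROC and AUC checks. For the probit model the recorded score is
#' the genetic score, which has correlation \eqn{\sqrt H} with liability.
#'
#' @inheritParams simulate_sib_pairs
#' @param n Number of subjects.
#' @return A data frame with columns `score` and `y`.
#' @export
simulate_subjects <- function(model, n, seed = NULL) {
  UseMethod("simulate_subjects")
}

#' @export
simulate_subjects.loglink_model <- function(model, n, seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    risk <- pmin(1, exp(model$c0 + model$alpha * x))
    data.frame(score = x, y = stats::rbinom(n, 1, risk))
  })
}

#' @export
simulate_subjects.quadlog_model <- function(model, n, seed = NULL) {
  with_seed(seed, {
    x <- stats::rnorm(n)
    risk <- pmin(1, exp(model$c0 + model$c1 * x + model$c2 * x^2))
    data.frame(score = x, y = stats::rbinom(n, 1, risk))
  })
}

#' @export
simulate_subjects.isc_model <- function(model, n, seed = NULL) {
  with_seed(seed, {
    x <- stats::rpois(n, model$mu)
    risk <- 1 - (1 - model$b) * (1 - model$p)^x
    data.frame(score = x, y = stats::rbinom(n, 1, risk))
  })
}

#' @export
simulate_subjects.probit_model <- function(model, n, seed = NULL) {
  with_seed(seed, {
    g <- stats::rnorm(n)
    L <- sqrt(model$H) * g + sqrt(1 - model$H) * stats::rnorm(n)
    data.frame(score = g, y = as.integer(L > model$T))
  })
}

#' Empirical AUC from scored subjects
#'
#' Rank-based (Wilcoxon) estimate of the probability that a random case
#' scores above a random non-case, with ties counted half.
#'
#' @param score Numeric scores.
#' @param y 0/1 outcomes.
#' @return The empirical AUC.
#' @export
empirical_auc <- function(score, y) {
  n1 <- as.numeric(sum(y == 1)); n0 <- as.numeric(sum(y == 0))
  if (n1 == 0 || n0 == 0) stop("need both cases and non-cases")
  r <- rank(score)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
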