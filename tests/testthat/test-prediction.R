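test_that("log-link recurrence ratio closed form and inverse", {
  expect_equal(loglink_lambda_s(0), 1)
  expect_equal(loglink_alpha_from_lambda_s(loglink_lambda_s(2.1)), 2.1, tolerance = 1e-12)
  expect_equal(loglink_lambda_s(loglink_alpha_from_lambda_s(10)), 10, tolerance = 1e-12)
  expect_error(loglink_alpha_from_lambda_s(0.9), "at least 1")
  expect_error(loglink_lambda_s(-1), "non-negative")
})

test_that("log-link lambda_S agrees with a sibling-pair Monte-Carlo oracle", {
  m <- loglink_model(P = 0.005, lambda_s = 3)
  sim <- simulate_sib_pairs(m, 4e5, seed = 51)
  expect_lt(abs(sim$lambda_s_hat - 3), 3 * sim$lambda_s_se)
  expect_lt(abs(sim$P_hat - 0.005), 3 * sim$P_se)
  # risk capping is rare at these settings and is reported
  expect_lt(sim$capped_fraction, 1e-4)
})

test_that("log-link ROC: degenerate and ordered cases, analytic vs empirical AUC", {
  # no genetic effect: diagonal ROC
  r0 <- loglink_roc(loglink_model(P = 0.005, alpha = 0))
  expect_equal(auc(r0), 0.5, tolerance = 1e-6)
  expect_lt(max(abs(r0$fpr - r0$tpr)), 1e-8)
  # AUC increases with heritability at fixed P
  aucs <- sapply(c(1.5, 3, 10), function(ls)
    auc(loglink_roc(loglink_model(P = 0.005, lambda_s = ls))))
  expect_true(all(diff(aucs) > 0))
  # analytic AUC matches the empirical AUC of simulated subjects
  m <- loglink_model(P = 0.005, lambda_s = 3)
  d <- simulate_subjects(m, 4e5, seed = 52)
  expect_lt(abs(auc(loglink_roc(m)) - empirical_auc(d$score, d$y)), 0.01)
  # fraction of implied risks above one: closed form vs direct probability
  expect_equal(m$fraction_risk_above_one,
               pnorm(-m$c0 / m$alpha, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("independent sufficient causes closed forms", {
  expect_equal(isc_population_risk(isc_model(mu = 5, p = 0, b = 0.02)), 0.02)
  expect_equal(isc_population_risk(isc_model(mu = 0, p = 0.5, b = 0)), 0)
  expect_equal(isc_lambda_s(isc_model(mu = 4, p = 0, b = 0.1)), 1)  # no heritable part
  # locus-heterogeneity regime: lambda_S approaches 1/(2P)
  m <- isc_model(mu = 2e-4, p = 1, b = 0)
  P <- isc_population_risk(m)
  expect_equal(isc_lambda_s(m) * 2 * P, 1, tolerance = 1e-3)
  # P and lambda_S against Monte-Carlo
  m2 <- isc_model(mu = 5, p = 0.1, b = 0.01)
  d <- simulate_subjects(m2, 2e5, seed = 53)
  P2 <- isc_population_risk(m2)
  expect_lt(abs(mean(d$y) - P2), 3 * sqrt(P2 * (1 - P2) / 2e5))
  sim <- simulate_sib_pairs(m2, 2e5, seed = 54)
  expect_lt(abs(sim$lambda_s_hat - isc_lambda_s(m2)), 3 * sim$lambda_s_se)
  # matched-(P, lambda_s) solving round-trips
  m3 <- isc_model(P = 0.01, lambda_s = 4, b = 0)
  expect_equal(isc_population_risk(m3), 0.01, tolerance = 1e-10)
  expect_equal(isc_lambda_s(m3), 4, tolerance = 1e-8)
  expect_error(isc_model(P = 0.01, lambda_s = 1000, b = 0), "unattainable")
})

test_that("ISC ROC geometry: perfect first step, diagonal, log-link proximity", {
  # rare fully penetrant variants: non-sporadic cases predicted perfectly
  r <- isc_roc(isc_model(mu = 0.01, p = 1, b = 0))
  i1 <- which(r$threshold == 1)
  expect_equal(r$tpr[i1], 1, tolerance = 1e-12)
  expect_lt(r$fpr[i1], 1e-6)
  # p = 0: scores carry no information
  r0 <- isc_roc(isc_model(mu = 5, p = 0, b = 0.02))
  expect_equal(auc(r0), 0.5, tolerance = 1e-9)
  # weakly heritable regime: ISC and log-link ROCs nearly coincide at
  # matched (P, lambda_S)
  P <- 0.05; ls <- 1.3
  mi <- isc_model(P = P, lambda_s = ls, b = 0)
  ml <- loglink_model(P = P, lambda_s = ls)
  expect_lt(abs(auc(isc_roc(mi)) - auc(loglink_roc(ml))), 0.02)
  # case counts exceed non-case counts on average
  ri <- isc_roc(mi)
  expect_gt(attr(ri, "mean_count_cases"), attr(ri, "mean_count_noncases"))
})

test_that("probit lambda_S: limits, inverse, monotonicity, Monte-Carlo", {
  expect_equal(probit_lambda_s(0, 0.01), 1, tolerance = 1e-9)
  expect_equal(probit_lambda_s(0, 0.2), 1, tolerance = 1e-9)
  H <- 0.6
  expect_equal(probit_H_from_lambda_s(probit_lambda_s(H, 0.01), 0.01), H,
               tolerance = 1e-8)
  expect_error(probit_H_from_lambda_s(1e6, 0.01), "unattainable")
  # strictly increasing in H at fixed P
  ls <- sapply(seq(0.1, 0.9, by = 0.2), probit_lambda_s, P = 0.01)
  expect_true(all(diff(ls) > 0))
  # sibling-pair Monte-Carlo oracle
  m <- probit_model(P = 0.01, H = 0.5)
  sim <- simulate_sib_pairs(m, 4e5, seed = 55)
  expect_lt(abs(sim$lambda_s_hat - m$lambda_s), 3 * sim$lambda_s_se)
})

test_that("probit ROC: diagonal at H = 0, improves with prevalence, beats log-link", {
  r0 <- probit_roc(probit_model(P = 0.01, H = 0))
  expect_equal(auc(r0), 0.5, tolerance = 1e-6)
  # at lambda_S = 10, prediction improves with increasing prevalence
  aucs <- sapply(c(1e-4, 1e-3, 1e-2), function(P)
    auc(probit_roc(probit_model(P = P, lambda_s = 10))))
  expect_true(all(diff(aucs) > 0))
  # and beats the multiplicative model at matched (P, lambda_S)
  expect_gt(aucs[1], auc(loglink_roc(loglink_model(P = 1e-4, lambda_s = 10))))
  # analytic ROC against empirical AUC of simulated genotype scores
  m <- probit_model(P = 0.01, H = 0.6)
  d <- simulate_subjects(m, 4e5, seed = 56)
  expect_lt(abs(auc(probit_roc(m)) - empirical_auc(d$score, d$y)), 0.01)
})

test_that("bivariate orthant probabilities are exact in known cases", {
  expect_equal(bvn_orthant(0, 0, 0), 0.25, tolerance = 1e-10)
  expect_equal(bvn_orthant(0, 0, 1), 0.5, tolerance = 1e-10)
  # Sheppard's formula: P(X>0, Y>0) = 1/4 + asin(rho)/(2 pi)
  for (rho in c(-0.8, -0.3, 0.2, 0.5, 0.9))
    expect_equal(bvn_orthant(0, 0, rho), 0.25 + asin(rho) / (2 * pi),
                 tolerance = 1e-9)
  # marginal consistency
  expect_equal(bvn_orthant(-Inf, 1.3, 0.4), pnorm(1.3, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("quadratic log-risk model nests the multiplicative model", {
  m0 <- quadlog_model(P = 0.005, c2 = 0, c1 = 1.2)
  ml <- loglink_model(P = 0.005, alpha = 1.2)
  expect_equal(m0$c0, ml$c0, tolerance = 1e-12)
  expect_equal(m0$lambda_s, ml$lambda_s, tolerance = 1e-12)
  expect_equal(auc(quadlog_roc(m0)), auc(loglink_roc(ml)), tolerance = 1e-4)
  expect_error(quadlog_model(P = 0.005, c2 = 0.4, c1 = 1), "1/3")
})

test_that("quadlog lambda_S Gaussian algebra agrees with 2-D quadrature", {
  for (cc in list(c(0.8, -0.1), c(1.2, 0.15))) {
    c1 <- cc[1]; c2 <- cc[2]
    tilt <- function(x) exp(c1 * x + c2 * x^2)
    # E over the sibling bivariate normal (rho = 1/2) by nested integration
    inner <- function(x1) sapply(x1, function(a)
      integrate(function(x2) tilt(x2) * dnorm(x2, 0.5 * a, sqrt(0.75)),
                -15, 15, rel.tol = 1e-10)$value)
    e_pair <- integrate(function(x1) tilt(x1) * dnorm(x1) * inner(x1),
                        -15, 15, rel.tol = 1e-9)$value
    e_one <- integrate(function(x) tilt(x) * dnorm(x), -15, 15,
                       rel.tol = 1e-10)$value
    expect_equal(quadlog_lambda_s(c1, c2), e_pair / e_one^2, tolerance = 1e-6)
  }
})

test_that("quadlog sib simulation matches the closed form", {
  m <- quadlog_model(P = 0.01, c2 = -0.08, lambda_s = 2.5)
  sim <- simulate_sib_pairs(m, 4e5, seed = 57)
  expect_lt(abs(sim$lambda_s_hat - 2.5), 3 * sim$lambda_s_se)
})

test_that("sub-multiplicative curvature improves prediction, supra worsens it", {
  P <- 0.005; ls <- 3
  a_multi <- auc(loglink_roc(loglink_model(P = P, lambda_s = ls)))
  a_sub <- auc(quadlog_roc(quadlog_model(P = P, c2 = -0.1, lambda_s = ls)))
  a_supra <- auc(quadlog_roc(quadlog_model(P = P, c2 = 0.1, lambda_s = ls)))
  expect_gt(a_sub, a_multi)
  expect_lt(a_supra, a_multi)
})

test_that("every model's ROC is monotone with proper endpoints and AUC >= 1/2", {
  rocs <- list(
    loglink_roc(loglink_model(P = 0.005, lambda_s = 5)),
    isc_roc(isc_model(mu = 3, p = 0.05, b = 0.002)),
    probit_roc(probit_model(P = 0.001, lambda_s = 4)),
    quadlog_roc(quadlog_model(P = 0.01, c2 = 0.05, lambda_s = 2)))
  for (r in rocs) {
    expect_true(all(diff(r$fpr) >= -1e-12))
    expect_true(all(diff(r$tpr) >= -1e-12))
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
    expect_gte(auc(r), 0.5)
  }
})

test_that("null sibling simulations give lambda_S near 1", {
  m <- loglink_model(P = 0.05, alpha = 0)
  sim <- simulate_sib_pairs(m, 2e5, seed = 58)
  expect_lt(abs(sim$lambda_s_hat - 1), 3 * sim$lambda_s_se)
})
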