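test_that("unit-weight single-stratum test equals the Cochran-Armitage table formula", {
  set.seed(11)
  for (rep in 1:20) {
    d <- random_cc_dataset(n_strata = 1, n_per = sample(8:16, 1))
    r <- suppressWarnings(linkscore_test(d, mode = "stratified"))
    o <- ca_table_oracle(d$y, d$x)
    expect_equal(r$U, o$U, tolerance = 1e-10)
    expect_equal(r$V, o$V, tolerance = 1e-10)
    expect_equal(r$statistic, o$chi2, tolerance = 1e-10)
  }
})

test_that("stratified V equals the exhaustive permutation variance", {
  set.seed(12)
  for (rep in 1:6) {
    d <- random_cc_dataset(n_strata = 2, n_per = sample(4:6, 1))
    w <- setNames(runif(2, 0.5, 3), levels(d$z))
    r <- suppressWarnings(linkscore_test(d, weight_scheme(w), mode = "stratified"))
    expect_equal(r$V, exhaustive_strat_var(d$y, d$x, d$z, w), tolerance = 1e-10)
  }
  # instance at the upper enumeration size: 7 subjects per stratum
  d <- random_cc_dataset(n_strata = 2, n_per = 7)
  r <- suppressWarnings(linkscore_test(d, mode = "stratified"))
  w1 <- setNames(c(1, 1), levels(d$z))
  expect_equal(r$V, exhaustive_strat_var(d$y, d$x, d$z, w1), tolerance = 1e-10)
})

test_that("marginal V equals the exhaustive whole-sample permutation variance", {
  set.seed(13)
  for (rep in 1:4) {
    d <- random_cc_dataset(n_strata = 2, n_per = 4)  # 8 subjects
    w <- setNames(runif(2, 0.5, 3), levels(d$z))
    r <- suppressWarnings(linkscore_test(d, weight_scheme(w), mode = "marginal"))
    expect_equal(r$V, exhaustive_marg_var(d$y, d$x, d$z, w), tolerance = 1e-10)
  }
})

test_that("marginal test with unit weights is the Cochran-Armitage test ignoring strata", {
  set.seed(14)
  d <- random_cc_dataset(n_strata = 3, n_per = 10)
  r <- linkscore_test(d, mode = "marginal")
  o <- ca_table_oracle(d$y, d$x)
  expect_equal(r$statistic, o$chi2, tolerance = 1e-10)
})

test_that("both tests are invariant to a global rescaling of weights", {
  set.seed(15)
  d <- random_cc_dataset(n_strata = 3, n_per = 12)
  w <- setNames(runif(3, 0.2, 5), levels(d$z))
  for (mode in c("stratified", "marginal")) {
    r1 <- linkscore_test(d, weight_scheme(w), mode = mode)
    r2 <- linkscore_test(d, weight_scheme(w * 7.3), mode = mode)
    expect_equal(r1$statistic, r2$statistic, tolerance = 1e-12)
    expect_equal(r1$p.value, r2$p.value, tolerance = 1e-12)
  }
})

test_that("weighted marginal statistic matches its reweighted-indicator definition", {
  set.seed(16)
  d <- random_cc_dataset(n_strata = 3, n_per = 15)
  w <- setNames(cc_weight(make_link("power_odds", 0.5),
                          pmin(pmax(tapply(d$y, d$z, mean), 0.1), 0.9)),
                levels(d$z))
  r <- linkscore_test(d, weight_scheme(w), mode = "marginal")
  yt <- w[as.character(d$z)] * d$y
  U <- sum((d$x - mean(d$x)) * (yt - mean(yt)))
  n <- nrow(d)
  V <- n^2 / (n - 1) * mean((d$x - mean(d$x))^2) * mean((yt - mean(yt))^2)
  expect_equal(r$statistic, U^2 / V, tolerance = 1e-12)
})

test_that("stratified and marginal U coincide when stratum genotype means are equal", {
  # two strata with identical genotype composition
  d <- cc_data(y = c(0, 1, 1, 0, 0, 1), x = c(0, 1, 2, 0, 1, 2), z = rep(1:2, each = 3))
  rs <- linkscore_test(d, mode = "stratified")
  rm <- linkscore_test(d, mode = "marginal")
  expect_equal(rs$U, rm$U, tolerance = 1e-12)
})

test_that("degenerate strata and constant genotypes are handled", {
  # constant x overall: statistic zero with a warning
  d <- cc_data(y = c(0, 1, 0, 1), x = rep(1, 4), z = c(1, 1, 2, 2))
  expect_warning(r <- linkscore_test(d, mode = "stratified"), "constant")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # single-subject strata contribute nothing
  d2 <- cc_data(y = c(0, 1, 1, 0, 1), x = c(0, 2, 1, 0, 2), z = c(1, 1, 1, 2, 3))
  d1 <- cc_data(y = c(0, 1, 1), x = c(0, 2, 1), z = c(1, 1, 1))
  r2 <- linkscore_test(d2, weight_scheme(setNames(c(1, 1, 1), 1:3)), "stratified")
  r1 <- linkscore_test(d1, mode = "stratified")
  expect_equal(r2$U, r1$U)
  expect_equal(r2$V, r1$V)
  expect_equal(r2$n_degenerate, 2L)
  # missing stratum weight is a configuration error
  expect_error(linkscore_test(d2, weight_scheme(setNames(c(1, 1), 1:2))),
               "no weight defined")
})

test_that("two-indicator test reduces to 1 df when one indicator is constant", {
  set.seed(17)
  y <- rbinom(40, 1, 0.5); x1 <- sample(0:1, 40, TRUE)
  d2 <- suppressWarnings(cc_data(y, x1, rep(1:2, 20), x2 = rep(1, 40)))
  d1 <- cc_data(y, x1, rep(1:2, 20))
  r2 <- suppressWarnings(linkscore_test(d2, mode = "stratified"))
  r1 <- linkscore_test(d1, mode = "stratified")
  expect_equal(r2$df, 1L)
  expect_equal(r2$statistic, r1$statistic, tolerance = 1e-10)
})

test_that("two-indicator stratified test agrees with the GLM Rao score test", {
  set.seed(18)
  n <- 2000
  z <- sample(1:3, n, TRUE, prob = c(0.5, 0.3, 0.2))
  g <- sample(0:2, n, TRUE, prob = c(0.25, 0.5, 0.25))
  eta <- c(-1.5, -0.5, 0.5)[z] + 0.12 * g
  y <- rbinom(n, 1, plogis(eta))
  x1 <- as.integer(g == 1); x2 <- as.integer(g == 2)
  d <- cc_data(y, x1, z, x2 = x2)
  r <- linkscore_test(d, mode = "stratified")
  f0 <- glm(y ~ factor(z), family = binomial)
  f1 <- glm(y ~ factor(z) + x1 + x2, family = binomial)
  rao <- anova(f0, f1, test = "Rao")$Rao[2]
  expect_equal(r$df, 2L)
  expect_equal(r$statistic, rao, tolerance = 0.02)
})

test_that("permutation p-values are reproducible and consistent with asymptotics", {
  set.seed(19)
  d <- random_cc_dataset(n_strata = 2, n_per = 30)
  r1 <- linkscore_test(d, mode = "stratified", n_perm = 500, seed = 42)
  r2 <- linkscore_test(d, mode = "stratified", n_perm = 500, seed = 42)
  expect_identical(r1$p_perm, r2$p_perm)
  expect_true(r1$p_perm >= 1 / 501 && r1$p_perm <= 1)
  expect_error(linkscore_test(d, n_perm = 50, seed = 1), "at least 100")

  # U = 0 data: permutation p must be 1
  d0 <- cc_data(y = c(0, 0, 0, 1, 1, 1), x = c(0, 1, 2, 0, 1, 2), z = rep(1, 6))
  r0 <- linkscore_test(d0, mode = "stratified", n_perm = 200, seed = 1)
  expect_equal(r0$U, 0)
  expect_equal(r0$p_perm, 1)

  # asymptotic and Monte-Carlo p agree on a moderate null dataset
  set.seed(20)
  dn <- cc_data(rbinom(500, 1, 0.5), sample(0:2, 500, TRUE), rep(1:2, 250))
  rn <- linkscore_test(dn, mode = "marginal", n_perm = 4000, seed = 7)
  se <- rn$perm_se
  expect_lt(abs(rn$p_perm - rn$p.value), 3 * se + 1e-3)
})

test_that("weighted marginal test is calibrated under the null (mean chi2 near 1)", {
  # strong Y-Z association, X independent of Z, correct probit weights
  sc <- scenario1()
  w <- optimal_weights(sc, "probit")
  set.seed(21)
  n_rep <- 400
  chi2 <- replicate(n_rep, {
    d <- simulate_cc_study(sc, "probit", beta = 0, N = 600)
    linkscore_test(d, weight_scheme(setNames(w, 1:7)), mode = "marginal")$statistic
  })
  # chi-squared(1) has variance 2
  expect_lt(abs(mean(chi2) - 1), 3 * sqrt(2 / n_rep))
})
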