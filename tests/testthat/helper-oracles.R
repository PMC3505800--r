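# Independent oracles used across the test files. These re-derive the test
# statistics from first principles (contingency-table formulas, exhaustive
# permutation enumeration) and must stay independent of the package internals.

# Cochran-Armitage trend test from the 2 x k contingency-table formula with
# the hypergeometric (Mantel) variance.
ca_table_oracle <- function(y, x) {
  s <- sort(unique(x))
  n_g <- as.numeric(table(factor(x, levels = s)))
  r_g <- as.numeric(tapply(y, factor(x, levels = s), sum))
  r_g[is.na(r_g)] <- 0
  N <- length(y); R <- sum(y)
  U <- sum(s * (r_g - n_g * R / N))
  V <- R * (N - R) / (N * (N - 1)) * (sum(n_g * s^2) - sum(n_g * s)^2 / N)
  list(U = U, V = V, chi2 = if (V > 0) U^2 / V else 0)
}

# all permutations of seq_len(n) (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive permutation variance of the weighted stratified U: strata are
# permuted independently, so the variances add
exhaustive_strat_var <- function(y, x, z, w) {
  tot <- 0
  for (lev in unique(z)) {
    i <- z == lev
    xz <- x[i]; yz <- y[i]; n <- sum(i)
    if (n < 2) next
    pm <- permutations(n)
    u <- apply(pm, 1, function(p) sum((xz[p] - mean(xz)) * (yz - mean(yz))))
    tot <- tot + unname(w[lev])^2 * mean(u^2)  # mean of U_z is 0 under permutation
  }
  tot
}

# exhaustive whole-sample permutation variance of the weighted marginal U
exhaustive_marg_var <- function(y, x, z, w) {
  yt <- w[as.character(z)] * y
  n <- length(y)
  pm <- permutations(n)
  u <- apply(pm, 1, function(p) sum((x[p] - mean(x)) * (yt - mean(yt))))
  mean(u^2) - mean(u)^2
}

# small random stratified case-control datasets
random_cc_dataset <- function(n_strata = 2, n_per = 6) {
  repeat {
    z <- rep(seq_len(n_strata), each = n_per)
    y <- rbinom(length(z), 1, 0.5)
    x <- sample(0:2, length(z), replace = TRUE)
    ok <- all(tapply(y, z, function(v) length(unique(v))) >= 1)
    if (ok && length(unique(x)) > 1 && length(unique(y)) > 1)
      return(cc_data(y, x, z))
  }
}

scenario1 <- function()
  population_scenario(c(0.1, 0.05, 0.02, 0.01, 0.005, 0.002, 0.001))
scenario2 <- function()
  population_scenario(c(0.05, 0.02, 0.01, 0.005))
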