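#' Weighted score tests for stratified case-control association
#'
#' Tests for association between a genotype score and case-control status in
#' the presence of a stratifying risk factor, allowing each stratum a positive
#' weight derived from an assumed population link function (see
#' [link_weight()]). With unit weights these are the classical tests: the
#' stratified test is the Mantel extension of the Cochran-Armitage trend test,
#' and the marginal test is the ordinary Cochran-Armitage test ignoring
#' strata. The marginal test assumes genotype is independent of stratum in the
#' population (usually reasonable for a new locus versus known risk factors)
#' and is generally more powerful under that assumption.
#'
#' The stratified statistic is
#' \deqn{U = \sum_z w_z \sum_{i \in z} (x_i - \bar x_z)(y_i - \bar y_z),}
#' with exact permutation variance (under within-stratum permutation)
#' \deqn{V = \sum_z w_z^2 \frac{n_z^2}{n_z - 1} S^2(x_z) S^2(y_z),}
#' where \eqn{S^2} is the divide-by-\eqn{n} sample variance. The marginal
#' statistic replaces the 0/1 indicator by \eqn{\tilde y_i = w_{z(i)} y_i} and
#' uses the whole-sample permutation variance
#' \eqn{V = N^2/(N-1)\, S^2(x) S^2(\tilde y)}. In both cases
#' \eqn{\chi^2 = U^2/V} is referred to a chi-squared distribution on 1 df.
#' When `data` carries two genotype indicators (`x`, `x2`) the vector score
#' and its permutation covariance matrix give a 2 df test (a generalized
#' inverse is used if the covariance is singular, with df reduced to its
#' rank).
#'
#' Strata with fewer than two subjects, or with constant genotype or constant
#' phenotype, contribute zero to both `U` and `V` of the stratified test;
#' their number is reported. Weights enter both statistics homogeneously, so
#' all results are invariant to rescaling all weights by a common factor.
#'
#' @param data A [cc_data()] object (two-indicator coding triggers the 2 df
#'   test).
#' @param weights A [weight_scheme()], a named per-stratum numeric vector, or
#'   a link (name or `"link_spec"`) from which weights are estimated via
#'   [estimate_weights()]. Default: unit weights.
#' @param mode `"stratified"` or `"marginal"`.
#' @param n_perm Number of random permutations for a Monte-Carlo p-value
#'   (0 = asymptotic only). Permutations are within-stratum for the
#'   stratified test and whole-sample for the marginal test.
#' @param seed Seed for the permutation p-value (required reproducibility
#'   contract when `n_perm > 0`).
#' @return An object of class `"linkscore_test"` with elements `statistic`
#'   (chi-squared), `df`, `p.value`, `U`, `V`, `mode`, `weights`
#'   (provenance string), `n`, `n_strata`, `n_degenerate`, and when
#'   `n_perm > 0` also `p_perm`, `perm_se`, `n_perm`, `seed`.
#' @examples
#' d <- cc_data(y = c(0, 0, 0, 1, 1, 1), x = c(0, 1, 2, 0, 1, 2), z = rep(1, 6))
#' linkscore_test(d)
#' @export
linkscore_test <- function(data, weights = unit_weights(data),
                           mode = c("stratified", "marginal"),
                           n_perm = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!inherits(data, "cc_data")) stop("'data' must be a cc_data object")
  w <- resolve_weights(data, weights)
  prov <- if (inherits(weights, "weight_scheme")) weights$provenance else "custom"
  two_df <- "x2" %in% names(data)
  X <- if (two_df) cbind(data$x, data$x2) else cbind(data$x)

  core <- function(xm, y, z) {
    if (mode == "stratified") strat_core(xm, y, z, w) else marg_core(xm, y, z, w)
  }
  obs <- core(X, data$y, data$z)

  constant_x <- all(apply(X, 2, function(col) length(unique(col)) == 1L))
  if (constant_x)
    warning("genotype score is constant; test statistic is zero")

  ev <- eigen(obs$V, symmetric = TRUE)
  tol <- max(ev$values, 0) * 1e-10
  pos <- ev$values > tol & ev$values > 0
  rank <- sum(pos)
  if (rank == 0L) {
    chi2 <- 0; df <- ncol(X); p <- 1
    if (!constant_x) warning("permutation variance is singular of rank 0; p = 1")
  } else {
    Vinv <- ev$vectors[, pos, drop = FALSE] %*%
      (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    chi2 <- drop(t(obs$U) %*% Vinv %*% obs$U)
    df <- rank
    p <- stats::pchisq(chi2, df = df, lower.tail = FALSE)
  }

  out <- structure(list(
    statistic = unname(chi2), df = df, p.value = unname(p),
    U = unname(drop(obs$U)), V = if (two_df) unname(obs$V) else unname(drop(obs$V)),
    mode = mode, weights = prov, n = nrow(data),
    n_strata = nlevels(data$z), n_degenerate = obs$n_degenerate),
    class = "linkscore_test")

  if (n_perm > 0) {
    if (n_perm < 100) stop("'n_perm' must be at least 100")
    quad <- function(u) if (rank == 0L) 0 else drop(t(u) %*% Vinv %*% u)
    t_obs <- quad(obs$U)
    idx_by_z <- split(seq_len(nrow(data)), data$z)
    hits <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        perm <- if (mode == "stratified")
          unsplit(lapply(idx_by_z, sample), data$z)
        else sample(nrow(data))
        quad(core(X[perm, , drop = FALSE], data$y, data$z)$U) >= t_obs - 1e-12
      }, logical(1)))
    })
    out$p_perm <- (1 + hits) / (1 + n_perm)
    out$perm_se <- sqrt(out$p_perm * (1 - out$p_perm) / n_perm)
    out$n_perm <- n_perm
    out$seed <- seed
  }
  out
}

strat_core <- function(X, y, z, w) {
  p <- ncol(X)
  U <- numeric(p); V <- matrix(0, p, p); ndeg <- 0L
  for (lev in levels(z)) {
    i <- which(z == lev)
    n_z <- length(i)
    if (n_z < 2L) { ndeg <- ndeg + 1L; next }
    xz <- X[i, , drop = FALSE]; yz <- y[i]
    sy <- s2(yz)
    Cx <- cov_biased(xz)
    if (sy == 0 || all(Cx == 0)) { ndeg <- ndeg + 1L; next }
    wc <- w[lev]
    yc <- yz - mean(yz)
    U <- U + wc * drop(crossprod(sweep(xz, 2, colMeans(xz)), yc))
    V <- V + wc^2 * n_z^2 / (n_z - 1) * Cx * sy
  }
  list(U = U, V = V, n_degenerate = ndeg)
}

marg_core <- function(X, y, z, w) {
  n <- length(y)
  yt <- w[as.character(z)] * y
  yc <- yt - mean(yt)
  U <- drop(crossprod(sweep(X, 2, colMeans(X)), yc))
  V <- n^2 / (n - 1) * cov_biased(X) * s2(yt)
  list(U = U, V = V, n_degenerate = 0L)
}

#' @export
print.linkscore_test <- function(x, ...) {
  cat(sprintf("Weighted %s score test (%s weights)\n", x$mode, x$weights))
  cat(sprintf("  chi-squared = %.4f, df = %d, p (asymptotic) = %.4g\n",
              x$statistic, x$df, x$p.value))
  if (!is.null(x$p_perm))
    cat(sprintf("  p (permutation, %d perms) = %.4g (MC se %.2g)\n",
                x$n_perm, x$p_perm, x$perm_se))
  cat(sprintf("  n = %d subjects in %d strata (%d non-contributing)\n",
              x$n, x$n_strata, x$n_degenerate))
  invisible(x)
}
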