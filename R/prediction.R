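#' ROC curves
#'
#' Internal-facing constructor for receiver operating characteristic curves:
#' ordered (FPR, TPR) pairs anchored at (0,0) and (1,1), with the area under
#' the curve computed by the trapezoid rule (equivalent to linear
#' interpolation between attainable operating points).
#'
#' @param fpr,tpr False/true positive rates at a sweep of thresholds.
#' @param thresholds Optional threshold values (same length).
#' @return A data frame of class `"roc_curve"` with attribute `"auc"`.
#' @export
roc_curve <- function(fpr, tpr, thresholds = NULL) {
  o <- order(fpr, tpr)
  fpr <- pmin(pmax(fpr[o], 0), 1)
  tpr <- pmin(pmax(tpr[o], 0), 1)
  thr <- if (is.null(thresholds)) rep(NA_real_, length(fpr)) else thresholds[o]
  fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1); thr <- c(Inf, thr, -Inf)
  tpr <- cummax(tpr)  # guard tiny numerical non-monotonicity
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            class = c("roc_curve", "data.frame"), auc = auc)
}

#' Area under a ROC curve
#' @param roc A `"roc_curve"`.
#' @return The AUC.
#' @export
auc <- function(roc) attr(roc, "auc")

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "false positive rate", ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Standard bivariate normal upper-orthant probability
#'
#' \eqn{P(X > a, Y > b)} for standard bivariate normal \eqn{(X, Y)} with
#' correlation `rho`, computed by the exact one-dimensional reduction
#' \eqn{\int_a^\infty \phi(x)\,\Phi\!\big((\rho x - b)/\sqrt{1-\rho^2}\big)dx}
#' with adaptive quadrature (relative tolerance 1e-10). Vectorized over `a`.
#'
#' @param a,b Lower limits.
#' @param rho Correlation in [-1, 1].
#' @return Orthant probability/ies.
#' @export
bvn_orthant <- function(a, b, rho) {
  if (abs(rho) > 1) stop("'rho' must lie in [-1, 1]")
  one <- function(a1) {
    if (rho == 1) return(stats::pnorm(max(a1, b), lower.tail = FALSE))
    if (rho == -1) return(max(0, stats::pnorm(-b) - stats::pnorm(a1)))
    if (rho == 0) return(stats::pnorm(a1, lower.tail = FALSE) *
                           stats::pnorm(b, lower.tail = FALSE))
    s <- sqrt(1 - rho^2)
    stats::integrate(function(x) stats::dnorm(x) * stats::pnorm((rho * x - b) / s),
                     lower = a1, upper = Inf,
                     rel.tol = 1e-10, abs.tol = 1e-13)$value
  }
  vapply(a, one, numeric(1))
}

# ---------------------------------------------------------------------------
# multiplicative (log link) model
# ---------------------------------------------------------------------------

#' Multiplicative (log-link) risk model
#'
#' A standard-normal genetic score `x` acts multiplicatively on risk:
#' \eqn{\log \pi(x) = c_0 + \alpha x}. With sibling scores bivariate normal
#' with correlation 1/2, the sibling recurrence risk ratio is
#' \eqn{\lambda_S = \exp(\alpha^2/2)} (independent of the population risk
#' `P`), and the score distribution among cases is exactly \eqn{N(\alpha,1)}.
#' Implied per-individual risks can exceed 1; the population fraction for
#' which they do is reported and risks are capped at 1 in ROC and simulation
#' computations.
#'
#' @param P Marginal population risk.
#' @param alpha Effect of the score on log risk (non-negative); give either
#'   this or `lambda_s`.
#' @param lambda_s Target sibling recurrence risk ratio (at least 1).
#' @return An object of class `"loglink_model"`.
#' @export
loglink_model <- function(P, alpha = NULL, lambda_s = NULL) {
  if (P <= 0 || P >= 1) stop("'P' must lie in (0, 1)")
  if (is.null(alpha)) {
    if (is.null(lambda_s)) stop("give 'alpha' or 'lambda_s'")
    alpha <- loglink_alpha_from_lambda_s(lambda_s)
  }
  if (alpha < 0) stop("'alpha' must be non-negative")
  c0 <- log(P) - alpha^2 / 2
  structure(list(P = P, alpha = alpha, c0 = c0,
                 lambda_s = loglink_lambda_s(alpha),
                 fraction_risk_above_one =
                   if (alpha == 0) as.numeric(P > 1)
                   else stats::pnorm(-c0 / alpha, lower.tail = FALSE)),
            class = "loglink_model")
}

#' @rdname loglink_model
#' @export
loglink_lambda_s <- function(alpha) {
  if (any(alpha < 0)) stop("'alpha' must be non-negative")
  exp(alpha^2 / 2)
}

#' @rdname loglink_model
#' @export
loglink_alpha_from_lambda_s <- function(lambda_s) {
  if (any(lambda_s < 1)) stop("'lambda_s' must be at least 1")
  sqrt(2 * log(lambda_s))
}

#' ROC curve for the multiplicative model
#'
#' Case score density is proportional to \eqn{\pi(x)\phi(x)} and non-case
#' density to \eqn{(1-\pi(x))\phi(x)}, with \eqn{\pi(x)} capped at 1;
#' sensitivity and the false positive rate (computed against non-cases) are
#' obtained by numeric integration over a fine score grid and swept over all
#' grid thresholds.
#'
#' @param model A [loglink_model()].
#' @param n_grid Number of integration grid points.
#' @return A [roc_curve()] with additional attribute
#'   `"fraction_risk_above_one"`.
#' @export
loglink_roc <- function(model, n_grid = 4001) {
  stopifnot(inherits(model, "loglink_model"))
  xs <- seq(-8, model$alpha + 9, length.out = n_grid)
  pi_x <- pmin(1, exp(model$c0 + model$alpha * xs))
  roc_from_grid(xs, pi_x, extra = c(fraction_risk_above_one =
                                      model$fraction_risk_above_one))
}

# shared grid sweep: risk pi(x) of a N(0,1) score, thresholds at grid points
roc_from_grid <- function(xs, pi_x, extra = NULL) {
  phi <- stats::dnorm(xs)
  fcase <- pi_x * phi
  fctrl <- (1 - pi_x) * phi
  h <- diff(xs)
  trap_rev <- function(f) {  # integral from x to upper end, at each grid point
    seg <- h * (utils::head(f, -1) + utils::tail(f, -1)) / 2
    c(rev(cumsum(rev(seg))), 0)
  }
  Pc <- trap_rev(fcase)[1]
  Pn <- trap_rev(fctrl)[1]
  tpr <- trap_rev(fcase) / Pc
  fpr <- trap_rev(fctrl) / Pn
  out <- roc_curve(fpr, tpr, thresholds = xs)
  if (!is.null(extra)) for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  attr(out, "P_marginal") <- Pc
  out
}

#' @export
print.loglink_model <- function(x, ...) {
  cat(sprintf("Multiplicative (log-link) model: P = %g, alpha = %.4f, lambda_S = %.4f\n",
              x$P, x$alpha, x$lambda_s))
  cat(sprintf("  fraction of population with implied risk > 1: %.3g\n",
              x$fraction_risk_above_one))
  invisible(x)
}

# ---------------------------------------------------------------------------
# independent sufficient causes model
# ---------------------------------------------------------------------------

#' Independent sufficient causes model
#'
#' An individual inherits \eqn{x \sim \mathrm{Poisson}(\mu)} risk variants,
#' each of which alone causes disease with penetrance `p`; a background
#' sporadic risk `b` acts as a further independent sufficient cause. The
#' per-individual risk is \eqn{1 - (1-b)(1-p)^x}; the marginal population
#' risk is \eqn{P = 1 - (1-b)e^{-\mu p}}. Sibling variant counts decompose
#' into a shared and two unshared Poisson components with means
#' \eqn{\mu/2, \mu/2, \mu/2}, giving a closed-form \eqn{\lambda_S}.
#' Alternatively specify a target `(P, lambda_s)` (with `b` fixed) and the
#' model solves for `(mu, p)`.
#'
#' @param mu Mean number of inherited risk variants.
#' @param p Penetrance of a single variant acting alone.
#' @param b Background (sporadic) risk.
#' @param P,lambda_s Target population risk and sibling recurrence ratio,
#'   used when `mu`/`p` are not given.
#' @return An object of class `"isc_model"`.
#' @export
isc_model <- function(mu = NULL, p = NULL, b = 0, P = NULL, lambda_s = NULL) {
  if (b < 0 || b > 1) stop("'b' must lie in [0, 1]")
  if (is.null(mu) || is.null(p)) {
    if (is.null(P) || is.null(lambda_s))
      stop("give ('mu','p') or ('P','lambda_s')")
    if (P <= b) stop("'P' must exceed the background risk 'b'")
    m <- -log((1 - P) / (1 - b))  # = mu * p
    ls_of_p <- function(pp) isc_lambda_s_closed(m / pp, pp, b)
    ls_max <- ls_of_p(1)
    if (lambda_s > ls_max)
      stop(sprintf("lambda_s = %g unattainable for P = %g, b = %g (max %.4f)",
                   lambda_s, P, b, ls_max))
    if (lambda_s < 1) stop("'lambda_s' must be at least 1")
    p <- if (abs(lambda_s - ls_max) < 1e-12) 1 else
      stats::uniroot(function(pp) ls_of_p(pp) - lambda_s,
                     c(1e-10, 1), tol = 1e-12)$root
    mu <- m / p
  }
  if (mu < 0) stop("'mu' must be non-negative")
  if (p < 0 || p > 1) stop("'p' must lie in [0, 1]")
  structure(list(mu = mu, p = p, b = b), class = "isc_model")
}

#' Marginal population risk under the independent sufficient causes model
#' @param model An [isc_model()].
#' @return \eqn{P = 1 - (1-b)e^{-\mu p}}.
#' @export
isc_population_risk <- function(model) {
  1 - (1 - model$b) * exp(-model$mu * model$p)
}

isc_lambda_s_closed <- function(mu, p, b) {
  P <- 1 - (1 - b) * exp(-mu * p)
  if (P == 0) stop("population risk is zero; lambda_S undefined")
  # E[(1-p)^(x1+x2)] over shared/unshared Poisson(mu/2) components
  e_pair <- exp(-mu / 2 * (1 - (1 - p)^2) - mu * p)
  (1 - 2 * (1 - b) * exp(-mu * p) + (1 - b)^2 * e_pair) / P^2
}

#' Sibling recurrence risk ratio under the independent sufficient causes model
#' @param model An [isc_model()].
#' @return \eqn{\lambda_S}, evaluated in closed form through the probability
#'   generating functions of the shared and unshared Poisson variant counts.
#' @export
isc_lambda_s <- function(model) {
  isc_lambda_s_closed(model$mu, model$p, model$b)
}

#' ROC curve for the independent sufficient causes model
#'
#' The genotype score is the variant count, so only integer thresholds are
#' attainable; sensitivity and false positive rate at each threshold are
#' exact Poisson-mixture sums, and the AUC interpolates linearly between
#' attainable operating points.
#'
#' @param model An [isc_model()].
#' @return A [roc_curve()] with attributes `"mean_count_cases"` and
#'   `"mean_count_noncases"`.
#' @export
isc_roc <- function(model) {
  mu <- model$mu; p <- model$p; b <- model$b
  P <- isc_population_risk(model)
  kmax <- max(5, stats::qpois(1 - 1e-14, mu) + 2)
  k <- 0:kmax
  pk <- stats::dpois(k, mu)
  risk <- 1 - (1 - b) * (1 - p)^k
  pcase <- pk * risk
  pctrl <- pk * (1 - risk)
  # threshold "x >= t" for integer t = 0..kmax+1
  tail_case <- rev(cumsum(rev(pcase)))
  tail_ctrl <- rev(cumsum(rev(pctrl)))
  tpr <- c(tail_case, 0) / P
  fpr <- c(tail_ctrl, 0) / (1 - P)
  out <- roc_curve(fpr, tpr, thresholds = c(k, kmax + 1))
  attr(out, "mean_count_cases") <- sum(k * pcase) / P
  attr(out, "mean_count_noncases") <- sum(k * pctrl) / (1 - P)
  out
}

#' @export
print.isc_model <- function(x, ...) {
  cat(sprintf(paste0("Independent sufficient causes model: mu = %.4g, p = %.4g,",
                     " b = %.4g\n  P = %.4g, lambda_S = %.4f\n"),
              x$mu, x$p, x$b, isc_population_risk(x), isc_lambda_s(x)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# probit (liability threshold) model
# ---------------------------------------------------------------------------

#' Liability threshold (probit) model
#'
#' Disease occurs when a standard-normal liability, the sum of independent
#' genetic and environmental N(0,1) scores weighted so that heritability of
#' liability is `H`, exceeds the threshold \eqn{T = \Phi^{-1}(1-P)}. Sibling
#' liabilities are bivariate normal with correlation \eqn{H/2}, so
#' \eqn{\lambda_S = \Phi_2(L_1 > T, L_2 > T; H/2)/P^2}; the genotype score
#' has correlation \eqn{\sqrt H} with liability, which gives the ROC curve.
#'
#' @param P Marginal population risk.
#' @param H Heritability of liability in [0, 1]; give either this or
#'   `lambda_s` (solved by root finding, with a domain error when the target
#'   exceeds the value at `H = 1`).
#' @param lambda_s Target sibling recurrence risk ratio.
#' @return An object of class `"probit_model"`.
#' @export
probit_model <- function(P, H = NULL, lambda_s = NULL) {
  if (P <= 0 || P >= 1) stop("'P' must lie in (0, 1)")
  if (is.null(H)) {
    if (is.null(lambda_s)) stop("give 'H' or 'lambda_s'")
    H <- probit_H_from_lambda_s(lambda_s, P)
  }
  if (H < 0 || H > 1) stop("'H' must lie in [0, 1]")
  structure(list(P = P, H = H, T = stats::qnorm(1 - P),
                 lambda_s = probit_lambda_s(H, P)),
            class = "probit_model")
}

#' @rdname probit_model
#' @export
probit_lambda_s <- function(H, P) {
  T <- stats::qnorm(1 - P)
  bvn_orthant(T, T, H / 2) / P^2
}

#' @rdname probit_model
#' @export
probit_H_from_lambda_s <- function(lambda_s, P) {
  if (lambda_s < 1) stop("'lambda_s' must be at least 1")
  ls_max <- probit_lambda_s(1, P)
  if (lambda_s > ls_max)
    stop(sprintf("lambda_s = %g unattainable for P = %g (max at H = 1 is %.4f)",
                 lambda_s, P, ls_max))
  if (lambda_s == 1) return(0)
  stats::uniroot(function(h) probit_lambda_s(h, P) - lambda_s,
                 c(0, 1), tol = 1e-12)$root
}

#' ROC curve for the liability threshold model
#'
#' At genotype-score threshold `t`,
#' \eqn{TPR(t) = \Phi_2(g > t, L > T; \sqrt H)/P} and
#' \eqn{FPR(t) = (\Phi(-t) - \Phi_2(g > t, L > T; \sqrt H))/(1-P)}, computed
#' exactly against non-cases.
#'
#' @param model A [probit_model()].
#' @param thresholds Score thresholds to sweep.
#' @return A [roc_curve()].
#' @export
probit_roc <- function(model, thresholds = seq(-7, 7, length.out = 561)) {
  stopifnot(inherits(model, "probit_model"))
  orth <- bvn_orthant(thresholds, model$T, sqrt(model$H))
  tpr <- orth / model$P
  fpr <- (stats::pnorm(thresholds, lower.tail = FALSE) - orth) / (1 - model$P)
  roc_curve(fpr, tpr, thresholds = thresholds)
}

#' @export
print.probit_model <- function(x, ...) {
  cat(sprintf(paste0("Liability threshold (probit) model: P = %g, H = %.4f,",
                     " T = %.4f, lambda_S = %.4f\n"),
              x$P, x$H, x$T, x$lambda_s))
  invisible(x)
}

# ---------------------------------------------------------------------------
# quadratic-log (power link approximation) model
# ---------------------------------------------------------------------------

#' Quadratic log-risk model (small-exponent power link)
#'
#' For a rare disease a power transformation of risk with small exponent is
#' well approximated by a log-linear model quadratic in the N(0,1) genetic
#' score: \eqn{\log \pi(x) = c_0 + c_1 x + c_2 x^2}. Negative `c2` gives
#' sub-multiplicative risk accumulation, positive `c2` supra-multiplicative;
#' `c2 = 0` is exactly the multiplicative model. The intercept is solved so
#' the marginal risk equals `P`; the tilted Gaussian algebra requires
#' `c2 < 1/3` for sibling-pair integrability (correlation 1/2).
#'
#' @param P Marginal population risk.
#' @param c2 Quadratic coefficient (`c2 < 1/3`).
#' @param c1 Linear coefficient (non-negative); give either this or
#'   `lambda_s`, in which case `c1` is solved at fixed `c2`.
#' @param lambda_s Target sibling recurrence risk ratio.
#' @return An object of class `"quadlog_model"`.
#' @export
quadlog_model <- function(P, c2 = 0, c1 = NULL, lambda_s = NULL) {
  if (P <= 0 || P >= 1) stop("'P' must lie in (0, 1)")
  if (c2 >= 1/3)
    stop("'c2' must be below 1/3 (tilted sibling density not integrable)")
  if (is.null(c1)) {
    if (is.null(lambda_s)) stop("give 'c1' or 'lambda_s'")
    if (lambda_s < quadlog_lambda_s(0, c2))
      stop("'lambda_s' below the value at c1 = 0 for this 'c2'")
    c1 <- stats::uniroot(function(cc) quadlog_lambda_s(cc, c2) - lambda_s,
                         c(0, 20), tol = 1e-12, extendInt = "upX")$root
  }
  if (c1 < 0) stop("'c1' must be non-negative")
  # marginal tilt: E[exp(c1 x + c2 x^2)] for x ~ N(0,1)
  m1 <- (1 - 2 * c2)^(-1 / 2) * exp(c1^2 / (2 * (1 - 2 * c2)))
  c0 <- log(P) - log(m1)
  structure(list(P = P, c1 = c1, c2 = c2, c0 = c0,
                 lambda_s = quadlog_lambda_s(c1, c2)),
            class = "quadlog_model")
}

#' @rdname quadlog_model
#' @export
quadlog_lambda_s <- function(c1, c2) {
  if (c2 >= 1/3) stop("'c2' must be below 1/3")
  Sigma <- matrix(c(1, 0.5, 0.5, 1), 2)
  M <- diag(2) - 2 * c2 * Sigma
  b <- c(c1, c1)
  e_pair <- det(M)^(-1 / 2) * exp(drop(b %*% solve(M, Sigma %*% b)) / 2)
  e_one <- (1 - 2 * c2)^(-1 / 2) * exp(c1^2 / (2 * (1 - 2 * c2)))
  e_pair / e_one^2
}

#' ROC curve for the quadratic log-risk model
#'
#' Same grid-integration sweep as [loglink_roc()], with per-individual risk
#' \eqn{\exp(c_0 + c_1 x + c_2 x^2)} capped at 1.
#'
#' @param model A [quadlog_model()].
#' @param n_grid Number of integration grid points.
#' @return A [roc_curve()] with attribute `"fraction_risk_above_one"`.
#' @export
quadlog_roc <- function(model, n_grid = 4801) {
  stopifnot(inherits(model, "quadlog_model"))
  xs <- seq(-10, 14, length.out = n_grid)
  logrisk <- model$c0 + model$c1 * xs + model$c2 * xs^2
  pi_x <- pmin(1, exp(logrisk))
  frac <- {
    hi <- logrisk > 0
    if (!any(hi)) 0 else sum(stats::dnorm(xs)[hi]) * (xs[2] - xs[1])
  }
  roc_from_grid(xs, pi_x, extra = c(fraction_risk_above_one = frac))
}

#' @export
print.quadlog_model <- function(x, ...) {
  cat(sprintf(paste0("Quadratic log-risk model: P = %g, c1 = %.4f, c2 = %.4f,",
                     " lambda_S = %.4f\n"),
              x$P, x$c1, x$c2, x$lambda_s))
  invisible(x)
}
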