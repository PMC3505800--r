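#' Binomial regression with an arbitrary risk link
#'
#' Maximum-likelihood fitting of a Bernoulli GLM whose mean is
#' \eqn{g^{-1}(X\beta)} for any of the link functions of [make_link()],
#' including the full power-odds (Box-Cox odds) family. In a case-control
#' sample the power-odds link may be applied directly to the case-control
#' probabilities: case-control sampling shifts the odds by the constant
#' sampling ratio, which for this family rescales the linear predictor but
#' does not leave the family, so the sampling ratio need not be known.
#'
#' Fitting is by iteratively reweighted least squares with step-halving:
#' because non-canonical links are not self-concordant, a full IRLS step can
#' overshoot, so any step that decreases the log-likelihood (or drives fitted
#' probabilities to the boundary) is halved until it does not. Convergence is
#' declared when the relative change in log-likelihood falls below `tol`.
#'
#' @param formula Model formula for the linear predictor.
#' @param data Data frame containing the variables (the response must be
#'   0/1).
#' @param link A `"link_spec"` or link name; `lambda` is passed through for
#'   `"power_odds"`.
#' @param lambda Power-odds exponent (when `link = "power_odds"`).
#' @param start Optional starting coefficient vector.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return An object of class `"po_glm"`: coefficients, fitted values, the
#'   maximized log-likelihood, convergence and separation flags, and the
#'   expected-information covariance of the coefficients.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = rnorm(500))
#' d$y <- rbinom(500, 1, plogis(-1 + d$x))
#' fit <- po_glm(y ~ x, d, link = "power_odds", lambda = 0.2)
#' coef(fit)
#' @export
po_glm <- function(formula, data, link = "logit", lambda = NULL,
                   start = NULL, tol = 1e-10, maxit = 100L) {
  link <- as_link(link, lambda = lambda)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (!all(y %in% c(0, 1))) stop("response must be coded 0/1")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- po_glm_fit(as.numeric(y), X, link, start = start, tol = tol, maxit = maxit)
  fit$call <- match.call()
  fit$formula <- formula
  fit
}

#' Workhorse fitter on a response vector and design matrix
#'
#' @param y 0/1 response vector.
#' @param X Numeric design matrix (full rank).
#' @inheritParams po_glm
#' @return A `"po_glm"` object.
#' @export
po_glm_fit <- function(y, X, link, start = NULL, tol = 1e-10, maxit = 100L) {
  link <- as_link(link)
  eps <- 1e-10
  n <- length(y); p <- ncol(X)
  ll <- function(mu) sum(y * log(mu) + (1 - y) * log(1 - mu))
  mu_of <- function(beta) pmin(pmax(link$g_inverse(drop(X %*% beta)), eps), 1 - eps)

  beta <- if (!is.null(start)) start else {
    b0 <- numeric(p)
    icpt <- which(apply(X, 2, function(c) all(c == 1)))[1]
    if (!is.na(icpt)) b0[icpt] <- link$g(mean(y))
    b0
  }
  mu <- mu_of(beta)
  ll_old <- ll(mu)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    gp <- link$g_prime(mu)                  # d eta / d mu
    wirls <- 1 / (gp^2 * mu * (1 - mu))     # expected-information weights
    zwork <- drop(X %*% beta) + (y - mu) * gp
    beta_new <- stats::lm.wfit(X, zwork, wirls)$coefficients
    if (any(!is.finite(beta_new))) { warning("IRLS produced non-finite step"); break }
    step <- beta_new - beta
    s <- 1
    repeat {
      cand <- beta + s * step
      ll_new <- ll(mu_of(cand))
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      s <- s / 2
      if (s < 1e-10) { ll_new <- ll_old; cand <- beta; break }
    }
    beta <- cand
    mu <- mu_of(beta)
    done <- abs(ll_new - ll_old) < tol * (abs(ll_old) + 0.1)
    ll_old <- ll_new
    if (done) { converged <- TRUE; break }
  }
  if (!converged)
    warning("po_glm_fit did not converge in ", maxit, " iterations")
  separated <- any(mu <= eps * 1.01 | mu >= 1 - eps * 1.01)
  if (separated)
    warning("fitted probabilities numerically at 0 or 1; possible separation")
  gp <- link$g_prime(mu)
  info <- crossprod(X * sqrt(1 / (gp^2 * mu * (1 - mu))))
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    fitted.values = mu, loglik = ll_old, link = link,
    converged = converged, separated = separated, iter = it,
    vcov = vcov, y = y, X = X, n = n),
    class = "po_glm")
}

#' @export
coef.po_glm <- function(object, ...) object$coefficients

#' @export
logLik.po_glm <- function(object, ...)
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")

#' @export
fitted.po_glm <- function(object, ...) object$fitted.values

#' @export
vcov.po_glm <- function(object, ...) object$vcov

#' @export
predict.po_glm <- function(object, newX = NULL, type = c("link", "response"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newX)) object$X else as.matrix(newX)
  eta <- drop(X %*% object$coefficients)
  if (type == "link") eta else object$link$g_inverse(eta)
}

#' @export
residuals.po_glm <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$y; mu <- object$fitted.values
  if (type == "pearson") return((y - mu) / sqrt(mu * (1 - mu)))
  d <- -2 * (y * log(mu) + (1 - y) * log(1 - mu))
  sign(y - mu) * sqrt(pmax(d, 0))
}

#' @export
print.po_glm <- function(x, ...) {
  print(x$link)
  cat("Coefficients:\n"); print(round(x$coefficients, 6))
  cat(sprintf("log-likelihood %.4f on %d observations (%sconverged, %d iterations)\n",
              x$loglik, x$n, if (x$converged) "" else "NOT ", x$iter))
  invisible(x)
}

#' @export
summary.po_glm <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  zval <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = zval,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(zval)))
  out <- list(link = object$link, coefficients = tab, loglik = object$loglik,
              n = object$n, converged = object$converged)
  class(out) <- "summary.po_glm"
  out
}

#' @export
print.summary.po_glm <- function(x, ...) {
  print(x$link)
  stats::printCoefmat(x$coefficients)
  cat(sprintf("log-likelihood %.4f on %d observations\n", x$loglik, x$n))
  invisible(x)
}

#' Profile likelihood for the power-odds link exponent
#'
#' Refits the binomial regression at each value of the power-odds exponent
#' \eqn{\lambda} on a grid (re-estimating all regression coefficients each
#' time, warm-started along the grid) and returns the profile log-likelihood,
#' the maximum-likelihood \eqn{\lambda} (grid maximum refined by a local
#' quadratic fit), and a likelihood-ratio confidence set
#' \eqn{\{\lambda : 2(\ell_{max} - \ell(\lambda)) \le \chi^2_1(level)\}}.
#'
#' @inheritParams po_glm
#' @param lambda_grid Ordered grid of exponents (at least 3 points;
#'   \eqn{\lambda = 0} is the logistic model).
#' @param level Confidence level for the likelihood-ratio set.
#' @return An object of class `"po_profile"`: `lambda_grid`, `loglik`,
#'   `lambda_mle`, `loglik_mle`, `ci` (interval endpoints when the set is
#'   contiguous on the grid, otherwise `NA` with the member grid points in
#'   `ci_grid`), and the fit at the MLE in `fit_mle`.
#' @export
profile_lambda <- function(formula, data,
                           lambda_grid = seq(-0.3, 0.5, by = 0.05),
                           level = 0.95, tol = 1e-10, maxit = 100L) {
  if (length(lambda_grid) < 3L) stop("'lambda_grid' must contain at least 3 points")
  lambda_grid <- sort(lambda_grid)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit_at <- function(lam, start = NULL)
    tryCatch(po_glm_fit(y, X, make_link("power_odds", lam),
                        start = start, tol = tol, maxit = maxit),
             warning = function(w) {
               f <- suppressWarnings(po_glm_fit(y, X, make_link("power_odds", lam),
                                                start = start, tol = tol, maxit = maxit))
               f$warned <- conditionMessage(w); f
             })
  lls <- rep(NA_real_, length(lambda_grid))
  start <- NULL
  for (i in seq_along(lambda_grid)) {
    f <- fit_at(lambda_grid[i], start = start)
    if (f$converged) { lls[i] <- f$loglik; start <- f$coefficients }
  }
  ok <- is.finite(lls)
  if (!any(ok)) stop("no grid point converged")
  if (any(!ok))
    warning(sum(!ok), " grid point(s) failed to converge and were excluded")
  grid <- lambda_grid[ok]; lls_ok <- lls[ok]
  i_max <- which.max(lls_ok)
  lam_mle <- grid[i_max]; ll_mle <- lls_ok[i_max]
  if (i_max > 1L && i_max < length(grid)) {
    xs <- grid[(i_max - 1):(i_max + 1)]; ys <- lls_ok[(i_max - 1):(i_max + 1)]
    co <- stats::lm.fit(cbind(1, xs, xs^2), ys)$coefficients
    if (is.finite(co[3]) && co[3] < 0) {
      vert <- -co[2] / (2 * co[3])
      if (vert > xs[1] && vert < xs[3]) {
        f_v <- fit_at(vert)
        if (f_v$converged && f_v$loglik >= ll_mle) {
          lam_mle <- vert; ll_mle <- f_v$loglik
        }
      }
    }
  }
  cut <- ll_mle - stats::qchisq(level, df = 1) / 2
  inset <- lls_ok >= cut
  ci <- c(NA_real_, NA_real_)
  if (all(diff(which(inset)) == 1L)) {  # contiguous
    lo_i <- min(which(inset)); hi_i <- max(which(inset))
    interp <- function(i0, i1) {  # crossing between grid[i0] (out) and grid[i1] (in)
      grid[i0] + (cut - lls_ok[i0]) / (lls_ok[i1] - lls_ok[i0]) * (grid[i1] - grid[i0])
    }
    ci[1] <- if (lo_i == 1L) grid[1] else interp(lo_i - 1L, lo_i)
    ci[2] <- if (hi_i == length(grid)) grid[length(grid)] else interp(hi_i + 1L, hi_i)
  }
  structure(list(lambda_grid = grid, loglik = lls_ok,
                 lambda_mle = lam_mle, loglik_mle = ll_mle,
                 ci = ci, ci_grid = grid[inset], level = level,
                 fit_mle = fit_at(lam_mle)),
            class = "po_profile")
}

#' @export
print.po_profile <- function(x, ...) {
  cat("Profile likelihood for the power-odds exponent\n")
  cat(sprintf("  grid: %g to %g (%d points)\n",
              min(x$lambda_grid), max(x$lambda_grid), length(x$lambda_grid)))
  cat(sprintf("  lambda MLE = %.4f (profile log-likelihood %.4f)\n",
              x$lambda_mle, x$loglik_mle))
  if (all(is.finite(x$ci)))
    cat(sprintf("  %g%% LR confidence interval: [%.4f, %.4f]\n",
                100 * x$level, x$ci[1], x$ci[2]))
  else
    cat(sprintf("  %g%% LR confidence set (grid points): %s\n",
                100 * x$level, paste(round(x$ci_grid, 3), collapse = ", ")))
  invisible(x)
}

#' @export
confint.po_profile <- function(object, parm, level, ...) {
  m <- matrix(object$ci, nrow = 1,
              dimnames = list("lambda", c("lower", "upper")))
  m
}

#' @export
plot.po_profile <- function(x, ...) {
  graphics::plot(x$lambda_grid, x$loglik, type = "l",
                 xlab = expression(lambda), ylab = "profile log-likelihood", ...)
  graphics::abline(v = x$lambda_mle, lty = 2)
  graphics::abline(h = x$loglik_mle - stats::qchisq(x$level, 1) / 2, lty = 3)
  invisible(x)
}
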