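#' Construct a link function specification
#'
#' A link function \eqn{g} maps a population disease risk \eqn{\pi \in (0,1)}
#' to an unbounded linear-predictor scale on which covariate effects are
#' assumed additive. The choice of link determines how multiple risk factors
#' combine: the logit link gives multiplicative odds, the log link
#' multiplicative risks, the probit link an underlying normal liability, and
#' the independence link \eqn{g(\pi) = -\log(1-\pi)} the model of independent
#' sufficient causes. The power-odds family is the Box-Cox transform of the
#' odds, \eqn{g_\lambda(\pi) = ((\pi/(1-\pi))^\lambda - 1)/\lambda}, with
#' \eqn{\lambda = 0} defined by continuity as the logit.
#'
#' @param name One of `"logit"`, `"log"`, `"probit"`, `"identity"`,
#'   `"independence"`, `"power_odds"`. A string of the form
#'   `"power_odds:0.25"` is also accepted and supplies `lambda`.
#' @param lambda Exponent for the power-odds link; required when
#'   `name == "power_odds"` unless given in `name`, ignored otherwise.
#' @return An object of class `"link_spec"`: a list with elements `name`,
#'   `lambda`, and functions `g` (risk to linear predictor), `g_inverse`, and
#'   `g_prime` (derivative of `g` with respect to risk). Risks are clipped to
#'   `[1e-12, 1 - 1e-12]` before evaluation.
#' @examples
#' lk <- make_link("probit")
#' lk$g(0.01)
#' make_link("power_odds", lambda = 0.5)
#' @export
make_link <- function(name, lambda = NULL) {
  if (!is.character(name) || length(name) != 1L)
    stop("'name' must be a single link name")
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1L]]
    name <- parts[1L]
    lambda <- as.numeric(parts[2L])
    if (is.na(lambda)) stop("could not parse power-odds exponent in '", parts[2L], "'")
  }
  valid <- c("logit", "log", "probit", "identity", "independence", "power_odds")
  if (!name %in% valid)
    stop("unknown link '", name, "'; valid links: ", paste(valid, collapse = ", "))
  if (name == "power_odds") {
    if (is.null(lambda) || !is.finite(lambda))
      stop("the power-odds link requires a finite 'lambda'")
  } else lambda <- NULL

  fns <- switch(name,
    logit = list(
      g = function(pi) stats::qlogis(clip_risk(pi)),
      g_inverse = function(eta) stats::plogis(eta),
      g_prime = function(pi) { pi <- clip_risk(pi); 1 / (pi * (1 - pi)) }),
    log = list(
      g = function(pi) log(clip_risk(pi)),
      g_inverse = function(eta) clip_risk(exp(eta)),
      g_prime = function(pi) 1 / clip_risk(pi)),
    probit = list(
      g = function(pi) stats::qnorm(clip_risk(pi)),
      g_inverse = function(eta) stats::pnorm(eta),
      g_prime = function(pi) 1 / stats::dnorm(stats::qnorm(clip_risk(pi)))),
    identity = list(
      g = function(pi) clip_risk(pi),
      g_inverse = function(eta) clip_risk(eta),
      g_prime = function(pi) rep_len(1, length(pi))),
    independence = list(
      g = function(pi) -log(1 - clip_risk(pi)),
      g_inverse = function(eta) 1 - exp(-pmax(eta, 1e-12)),
      g_prime = function(pi) 1 / (1 - clip_risk(pi))),
    power_odds = if (lambda == 0) list(
      g = function(pi) stats::qlogis(clip_risk(pi)),
      g_inverse = function(eta) stats::plogis(eta),
      g_prime = function(pi) { pi <- clip_risk(pi); 1 / (pi * (1 - pi)) })
    else local({
      lam <- lambda
      # expm1/log1p forms stay accurate through the Box-Cox seam (small lam)
      list(
        g = function(pi) { pi <- clip_risk(pi); expm1(lam * stats::qlogis(pi)) / lam },
        g_inverse = function(eta) {
          stats::plogis(log1p(pmax(lam * eta, -1 + 1e-300)) / lam)
        },
        g_prime = function(pi) {
          pi <- clip_risk(pi)
          (pi / (1 - pi))^(lam - 1) / (1 - pi)^2
        })
    })
  )
  structure(
    list(name = name, lambda = lambda,
         g = fns$g, g_inverse = fns$g_inverse, g_prime = fns$g_prime),
    class = "link_spec")
}

clip_risk <- function(pi) pmin(pmax(pi, 1e-12), 1 - 1e-12)

#' Coerce to a link specification
#'
#' @param x A `"link_spec"` object or a link name string (optionally
#'   `"power_odds:<lambda>"`).
#' @param lambda Optional power-odds exponent when `x` is `"power_odds"`.
#' @return A `"link_spec"` object.
#' @export
as_link <- function(x, lambda = NULL) {
  if (inherits(x, "link_spec")) return(x)
  make_link(x, lambda = lambda)
}

#' @export
print.link_spec <- function(x, ...) {
  lab <- x$name
  if (!is.null(x$lambda)) lab <- sprintf("%s (lambda = %g)", lab, x$lambda)
  cat("Link function:", lab, "\n")
  invisible(x)
}

#' Map a case-control probability back to population risk
#'
#' Under case-control sampling with sampling-fraction ratio \eqn{K} (cases
#' relative to non-cases), the probability \eqn{\mu} of being a case in the
#' study sample and the population risk \eqn{\pi} of the corresponding stratum
#' are related by an odds shift: \eqn{\mathrm{logit}(\pi) =
#' \mathrm{logit}(\mu) - \log K}. The relation follows from Bayes' theorem and
#' does not depend on the assumed link function.
#'
#' @param mu Case probability in the study sample, in (0,1). Vectorized.
#' @param K Positive sampling ratio; `K = 1` is the identity.
#' @return Population risk(s) \eqn{\pi}.
#' @examples
#' cc_transform(0.5, K = 9)  # 0.1
#' @export
cc_transform <- function(mu, K = 1) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive number")
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0 | mu >= 1))
    stop("'mu' must lie strictly inside (0, 1)")
  stats::plogis(stats::qlogis(mu) - log(K))
}

#' Stratum weight implied by a link function at a population risk
#'
#' The efficient score test for a new variant, when risk follows a generalized
#' linear model with link \eqn{g} in the population, weights each stratum's
#' contribution by \eqn{W(\pi) = 1 / (g'(\pi)\,\pi\,(1-\pi))} evaluated at the
#' stratum's population risk. For the logit link the weight is constant (1):
#' the classical unweighted trend test is efficient only under the logistic
#' model. For the power-odds link the weight is \eqn{(\pi/(1-\pi))^{-\lambda}}:
#' \eqn{\lambda > 0} up-weights low-risk strata, \eqn{\lambda < 0} up-weights
#' high-risk strata. Weights are meaningful only up to a common positive
#' factor; all tests in this package are invariant to global rescaling.
#'
#' @param link A `"link_spec"` or link name.
#' @param pi Population risk(s), strictly in (0,1).
#' @return Positive weight(s), unnormalized.
#' @examples
#' link_weight("logit", c(0.01, 0.2))     # always 1
#' link_weight("probit", 0.5)             # dnorm(0) / 0.25
#' link_weight("independence", 0.5)       # 1 / pi = 2
#' @export
link_weight <- function(link, pi) {
  link <- as_link(link)
  if (!is.numeric(pi) || any(!is.finite(pi)) || any(pi <= 0 | pi >= 1))
    stop("'pi' must lie strictly inside (0, 1)")
  1 / (link$g_prime(pi) * pi * (1 - pi))
}

#' Stratum weight from a case-control case fraction
#'
#' Evaluates [link_weight()] at the population risk implied by the stratum's
#' case fraction \eqn{\mu} in the study and the sampling ratio \eqn{K}, i.e.
#' `link_weight(link, cc_transform(mu, K))`. For power-odds links the result
#' is \eqn{K^{\lambda}} times \eqn{(\mu/(1-\mu))^{-\lambda}}, a power of the
#' stratum-specific case:control odds, so the (usually unknown) sampling ratio
#' only rescales all weights by a common factor and need not be estimated.
#'
#' @inheritParams cc_transform
#' @param link A `"link_spec"` or link name.
#' @return Positive weight(s).
#' @export
cc_weight <- function(link, mu, K = 1) {
  link_weight(as_link(link), cc_transform(mu, K))
}

#' Power-odds exponent most closely matching the probit link
#'
#' Finds, by least squares over a grid of risks, the power-odds exponent
#' \eqn{\lambda} whose link function is most nearly an affine transform of the
#' probit link: it minimizes the residual sum of squares of the regression of
#' \eqn{\Phi^{-1}(\pi)} on \eqn{g_\lambda(\pi)} over the grid, normalized by
#' the total sum of squares.
#'
#' @param pi_grid Risks at which the two links are compared.
#' @param interval Search interval for \eqn{\lambda}.
#' @return The best-matching \eqn{\lambda}, with the achieved \eqn{R^2} as
#'   attribute `"r.squared"`.
#' @export
powerodds_approx_lambda <- function(pi_grid = seq(0.001, 0.5, length.out = 200),
                                    interval = c(-0.9, 0.9)) {
  y <- stats::qnorm(pi_grid)
  obj <- function(lam) {
    x <- make_link("power_odds", lam)$g(pi_grid)
    r <- stats::lm.fit(cbind(1, x), y)$residuals
    sum(r^2) / sum((y - mean(y))^2)
  }
  opt <- stats::optimize(obj, interval = interval)
  structure(opt$minimum, r.squared = 1 - opt$objective)
}
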