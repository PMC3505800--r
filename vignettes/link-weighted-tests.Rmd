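---
title: "Link functions, weighted trend tests, and genetic risk prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link functions, weighted trend tests, and genetic risk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkscore)
```

## The model

Disease risk in the population is assumed to follow a binomial generalized
linear model: for a subject in risk stratum $z$ (defined by known strong risk
factors) carrying genotype score $x$,

$$ g\{\pi_z(x)\} = \eta_z + \beta x, $$

where $g$ is a monotone *link function* mapping risk $\pi \in (0,1)$ to an
unbounded scale on which effects add. The choice of $g$ encodes how multiple
causes combine: the logit link gives multiplicative odds, the log link
multiplicative risks, the probit link an underlying normally distributed
liability with a threshold, and the independence link
$g(\pi) = -\log(1-\pi)$ the classical model of independent sufficient causes
(locus heterogeneity). Between these sits the power-odds (Box–Cox odds)
family
$$ g_\lambda(\pi) = \frac{\{\pi/(1-\pi)\}^{\lambda} - 1}{\lambda}, $$
with $\lambda = 0$ the logit by continuity, $\lambda > 0$ sub-multiplicative
risk accumulation (at $\lambda = 1$, odds — and for rare disease, risks —
add), and $\lambda < 0$ supra-multiplicative accumulation.

In a case-control study a stratum's case fraction $\mu$ and its population
risk $\pi$ are linked by the odds shift
$\mathrm{logit}\,\pi = \mathrm{logit}\,\mu - \log K$, where $K$ is the ratio
of the sampling fractions of cases and non-cases. This relation follows from
Bayes' theorem and holds whatever the link (`cc_transform()`).

## Stratum weights and the two score tests

The efficient score test for $\beta = 0$ weights each stratum by

$$ W(\pi) = \frac{1}{g'(\pi)\,\pi\,(1-\pi)}, $$

evaluated at the stratum's population risk (`link_weight()`). A single
formula covers every built-in link: the logit gives the constant weight 1
(the classical tests are efficient only under the logistic model), the
independence link gives $1/\pi$, the probit gives
$\phi\{\Phi^{-1}(\pi)\}/\{\pi(1-\pi)\}$ — nearly linear in
$\mathrm{logit}\,\pi$ and mildly favouring low-risk strata — and the
power-odds family gives $\{\pi/(1-\pi)\}^{-\lambda}$, a pure power of the
odds. The power-odds weights are special in practice: expressed through the
observed stratum case:control odds they absorb the unknown $K$ into a
constant factor, so no sampling-ratio estimate is needed
(`estimate_weights()`). Weights are kept unnormalized throughout; every
statistic in the package is invariant to a global rescaling, and the tests
assert this.

Two tests are provided by `linkscore_test()`. The **stratified** test
$$ U = \sum_z w_z \sum_{i\in z} (x_i - \bar x_z)(y_i - \bar y_z), \qquad
   V = \sum_z w_z^2 \frac{n_z^2}{n_z-1} S^2(x_z)\,S^2(y_z), $$
uses the exact variance of $U$ under independent within-stratum permutation
($S^2$ is the divide-by-$n$ variance); with unit weights it is the familiar
stratum-adjusted trend test. The **marginal** test assumes the variant is
independent of the stratifying factors in the population — the usual
situation for a new locus against established risk factors — and replaces
the case indicator by $\tilde y_i = w_{z(i)} y_i$ in the ordinary
unstratified trend statistic, with the whole-sample permutation variance
$V = N^2/(N-1)\,S^2(x)S^2(\tilde y)$. With unit weights it is exactly the
Cochran–Armitage test ignoring strata. A two-indicator genotype coding gives
the corresponding 2-df tests with a permutation covariance matrix; singular
covariances are handled by a generalized inverse with the degrees of freedom
reduced to the matrix rank. Monte-Carlo p-values use
$p = (1 + \#\{|U^{perm}| \ge |U^{obs}|\})/(1 + n_{perm})$ with the
permutation scheme matching the test's conditioning.

A deliberate design choice: the variance is defined as the *exact*
permutation variance (hence the $n_z - 1$ denominators), and the test suite
verifies it against brute-force enumeration of all permutations on instances
with up to seven subjects per stratum. Degenerate strata — a single subject,
or constant genotype or phenotype — contribute zero to both $U$ and $V$ and
are counted in the result.

## Fitting the power-odds exponent

`po_glm()` maximizes the Bernoulli likelihood for any built-in link by
iteratively reweighted least squares. The power-odds link is not canonical,
so a full IRLS step can overshoot; any step that decreases the
log-likelihood (or pins fitted probabilities at the numerical boundary) is
halved until it does not. Convergence is declared when the relative change
in log-likelihood falls below $10^{-10}$ (at most 100 iterations), and
boundary-pinned fits are flagged as possible separation. The transform and
its inverse are evaluated through `expm1`/`log1p`, which keeps the family
numerically smooth through $\lambda = 0$: the fitted log-likelihood is
continuous across the seam to well below $10^{-6}$.

`profile_lambda()` refits all regression coefficients at each grid value of
$\lambda$ (warm-starting along the grid), refines the grid maximum with a
local quadratic, and reports the likelihood-ratio confidence set
$\{\lambda: 2(\ell_{max} - \ell(\lambda)) \le \chi^2_1(0.95)\}$, interpolated
to an interval when contiguous. Because case-control sampling only shifts
the odds by the constant $K$, the power-odds family applied directly to the
case-control probabilities remains a power-odds model with rescaled
coefficients, so the profile needs no knowledge of $K$. The default grid
$-0.3$ to $0.5$ in steps of $0.05$ brackets the region between mildly
supra-multiplicative and additive-odds models; it is user-overridable.

## Asymptotic efficiency under link misspecification

For power calculations the study composition induced by case-control
sampling from a stratified population is computed exactly
(`cc_composition()`): cases arise from stratum $z$ with probability
$f_z\pi_z/\sum f\pi$, controls with probability $f_z(1-\pi_z)/\sum f(1-\pi)$,
mixed in the design's case:control ratio (default 1:1, the common design
choice, kept as a parameter so sensitivity can be checked).

The quantity of practical interest is the non-centrality parameter (NCP) of
the *weighted marginal* test in the small-effect limit, since the marginal
test is what one uses when the variant is independent of the strata. Its
local mean requires care: under case-control sampling an effect at the
tested locus induces an association between genotype and stratum *in the
sample* (cases are over-drawn from high-risk strata and carry more risk
alleles), so besides the within-stratum term
$\sum_z a_z \mu_z(1-\mu_z) w_z W^*_z$ the mean of $U$ carries a
between-stratum term in which the per-stratum genotype shift
$\beta\,\mathrm{Var}(x)\,W^*_z(\mu_z - \pi_z)$ covaries with
$E[\tilde y \mid z]$ across strata ($W^*$ denotes the weight function of the
generating link). The null variance is the whole-sample permutation variance
$\mathrm{Var}(x)\,\mathrm{Var}(\tilde y)$, which likewise includes the
between-stratum variance of $\tilde y$. Both terms were re-derived here and
validated two ways: against exact cell-probability enumeration of the
statistic's moments at $\beta = 10^{-4}$ (agreement to seven digits) and
against simulation at finite $\beta$ (the `ncp()` value matches the mean
excess chi-squared within Monte-Carlo error). `efficiency()` is the ratio of
this NCP at the analysis weights to its value at the optimal weights
$W^*(\pi_z)$; `ncp()` and `efficiency()` satisfy the ratio identity to
$10^{-12}$ by construction, and genotype variance $2\,\mathrm{maf}(1-\mathrm{maf})$
cancels in the ratio. The NCP of the stratified test (no between-stratum
terms) is available via `test = "stratified"`.

Two features of the resulting efficiency surface deserve comment, because
they are properties of the computation rather than assumptions:

* Under 1:1 case-control sampling the study information
  $a_z\mu_z(1-\mu_z)$ concentrates in the *high-risk* strata. Consequently a
  sub-multiplicative truth ($\lambda > 0$), whose optimal weights up-weight
  the information-poor low-risk strata, costs the unweighted test more than
  the mirrored supra-multiplicative truth at the same $|\lambda|$. The
  package's efficiency curves reflect this and the tests assert it.
* The two bundled scenarios (seven equal strata with risks 0.1–0.001;
  four equal strata with risks 0.05–0.005) give efficiency curves with the
  extreme scenario lower throughout the visibly misspecified region
  ($|\lambda| \gtrsim 0.15$); in a narrow band near the correctly specified
  point both curves are within 0.005 of 1 and their order is not meaningful
  at figure resolution.

## From heritability to predictability

The prediction half of the package asks: given a disease's sibling
recurrence risk ratio $\lambda_S$ (risk to a sibling of a case over the
population risk $P$), how well could genotype ever predict disease? The
answer depends strongly on the link. Four models are implemented, each
parameterizable either natively or by a target $(P, \lambda_S)$ so that
models can be compared at matched heritability. Every closed form below was
re-derived from the stated distributional assumptions and is guarded by a
seeded Monte-Carlo sibling-pair oracle in the test suite — the simulation,
not the algebra, is treated as ground truth.

* **Multiplicative (log link)** — `loglink_model()`: a standard-normal
  genetic score $x$ with $\log\pi(x) = c_0 + \alpha x$. Sibling scores are
  bivariate normal with correlation $1/2$, whence
  $\lambda_S = e^{\alpha^2/2}$ (the bivariate-normal moment identity
  $E\,e^{\alpha(x_1+x_2)} = e^{3\alpha^2/2}$ divided by
  $(E\,e^{\alpha x})^2 = e^{\alpha^2}$), independent of $P$. The case score
  distribution is exactly $N(\alpha, 1)$. Implied risks can exceed 1; the
  affected population fraction is reported, and ROC integration and the
  simulators truncate risk at 1. The intercept is set from the untruncated
  closed form $c_0 = \log P - \alpha^2/2$; at the small prevalences of
  interest the truncated fraction is of order $10^{-5}$.
* **Independent sufficient causes** — `isc_model()`: a
  $\mathrm{Poisson}(\mu)$ count of inherited risk variants, each alone
  penetrant with probability $p$, plus a sporadic background cause $b$, so
  that the per-subject risk is $1-(1-b)(1-p)^x$ and
  $P = 1 - (1-b)e^{-\mu p}$ by the Poisson generating function. Sibling
  counts share a $\mathrm{Poisson}(\mu/2)$ component with independent
  $\mathrm{Poisson}(\mu/2)$ remainders, giving a closed-form $\lambda_S$;
  as $\mu \to 0$ with $p = 1$ it approaches the locus-heterogeneity limit
  $\lambda_S \approx 1/(2P)$. The score is the integer variant count, so the
  ROC has attainable operating points only at integer thresholds; the AUC
  interpolates linearly between them. With rare, highly penetrant variants
  the first step of the curve captures essentially all non-sporadic cases.
* **Quadratic log-risk (small power exponent)** — `quadlog_model()`:
  $\log\pi(x) = c_0 + c_1 x + c_2 x^2$, the local approximation to a power
  transform of risk. The tilted Gaussian algebra gives $\lambda_S$ exactly
  via $E\exp(b^\top x + x^\top A x)$ for bivariate normal $x$ (verified
  against two-dimensional quadrature to $10^{-6}$); integrability of the
  sibling tilt requires $c_2 < 1/3$, enforced as a domain error. $c_2 = 0$
  collapses to the multiplicative model exactly. Sub-multiplicative
  curvature ($c_2 < 0$) improves prediction at matched $(P, \lambda_S)$;
  supra-multiplicative curvature worsens it.
* **Liability threshold (probit)** — `probit_model()`: liability is
  $N(0,1)$, disease is liability above $T = \Phi^{-1}(1-P)$, sibling
  liabilities correlate $H/2$ and the genotype score correlates $\sqrt H$
  with liability. Then $\lambda_S = \Phi_2(T, T; H/2)/P^2$ (upper orthant)
  and the ROC is $TPR(t) = \Phi_2(t, T; \sqrt H)/P$,
  $FPR(t) = \{\Phi(-t) - \Phi_2(t, T; \sqrt H)\}/(1-P)$. Bivariate normal
  orthant probabilities are computed by the exact one-dimensional reduction
  $\int_a^\infty \phi(x)\Phi\{(\rho x - b)/\sqrt{1-\rho^2}\}\,dx$ with
  adaptive quadrature at relative tolerance $10^{-10}$; `bvn_orthant()`
  reproduces Sheppard's arc-sine formula to $10^{-9}$. Inversion of
  $\lambda_S$ to $H$ is by bracketed root finding on $[0,1]$, with a domain
  error when the target exceeds the value at $H = 1$.

False positive rates are computed against non-cases exactly (not against the
whole population); at small $P$ the difference is negligible but the
convention is fixed for determinism. Continuous-score ROC curves are swept
over a fine fixed grid of thresholds (about 4000 integration nodes and 560
threshold points), which resolves AUC to well inside the 0.005 tolerance the
oracle tests use.

## The simulators

`simulate_cc_study()` embodies the generative model of the power
calculations: Hardy–Weinberg genotypes independent of stratum, effect
constant across strata on the generating link's scale, stratum intercepts
solved so the risk at the mean genotype equals the nominal stratum risk.
Rather than rejection-sampling a cohort, it computes the exact per-stratum
case and control genotype frequencies by Bayes inversion and multinomially
samples them to the design's case and control counts — so a 2000-subject
null study costs a few multinomial draws and thousands of replicates are
cheap. Configurations that push any attainable genotype's risk outside
$(0,1)$ are rejected with an error. All randomness flows through a single
seed argument that saves and restores the caller's RNG state.

`simulate_sib_pairs()` and `simulate_subjects()` provide the Monte-Carlo
oracles for the prediction models: bivariate normal scores (correlation
$1/2$) for the log-link and quadratic models, the shared/unshared Poisson
decomposition for the sufficient-causes model, and bivariate normal
liabilities (correlation $H/2$) or genotype scores (correlation $\sqrt H$
with liability) for the probit model. Log-link risks above 1 are truncated
with the truncated fraction reported.

### What the simulations do and do not establish

The generators reproduce exactly the idealized conditions of the theory:
discrete exchangeable strata, a single diallelic variant in
Hardy–Weinberg equilibrium independent of the strata, no linkage
disequilibrium, no genotyping error, and risk models that hold exactly.
Passing tests therefore demonstrate internal correctness of the formulas and
their implementation — not robustness to population structure, covariate
measurement error, LD between test and conditioning loci, or model
misspecification beyond the link function itself. The sample sizes used by
the test suite (null calibration at $N = 2000$ over 1000 replicates;
exponent recovery at $N$ = 5000–10000 over 100 replicates; prediction
oracles at $10^6$ pairs or subjects) were chosen to make Monte-Carlo error
comfortably smaller than the tolerances being asserted.

## Numerical choices and degenerate inputs

* Risks are clipped to $[10^{-12}, 1-10^{-12}]$ before link evaluation.
* The power-odds transform uses `expm1`/`log1p`; $\lambda = 0$ is the exact
  logit branch.
* IRLS uses expected-information weights with step-halving; the profile
  refits from warm starts and excludes (with a warning) any grid point that
  fails to converge.
* 2-df tests with singular permutation covariance use an eigenvalue
  generalized inverse at relative tolerance $10^{-10}$ with rank-reduced
  degrees of freedom; rank zero yields $p = 1$ with a warning.
* Ties in genotype scores are handled by the rank-based empirical AUC
  (ties count half), matching the linear interpolation used for the
  integer-threshold ROC.
* Degenerate strata (all-case, all-control, constant genotype, single
  subject) contribute zero and are counted in the returned object.

## Limitations

The package deliberately treats confounders as a discrete stratification; a
fitted-value hook for regression-based weights exists in the theory but no
modelling interface is provided for continuous covariate adjustment. Input
is single-variant tabular data, not genome-wide file formats. Recurrence
risks are computed for siblings only, and ascertainment corrections for
family sampling are out of scope.
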