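#' Stratified case-control data
#'
#' Container for single-variant case-control data: a 0/1 phenotype `y`, a
#' stratum label `z` (existing strong risk factors, e.g. HLA type), and a
#' numeric genotype score `x` (conventionally 0/1/2 with the heterozygote at
#' the midpoint; the tests are invariant to affine recoding). For the
#' 2-degree-of-freedom genotype test supply two indicator codings `x` and
#' `x2`.
#'
#' @param y 0/1 phenotype vector (1 = case).
#' @param x Numeric genotype score, or first genotype indicator.
#' @param z Stratum labels (coerced to factor).
#' @param x2 Optional second genotype indicator.
#' @return A data frame of class `"cc_data"`.
#' @export
cc_data <- function(y, x, z, x2 = NULL) {
  if (length(y) != length(x) || length(y) != length(z))
    stop("'y', 'x' and 'z' must have equal length")
  if (!is.null(x2) && length(x2) != length(y))
    stop("'x2' must have the same length as 'y'")
  if (!all(y %in% c(0, 1)))
    stop("phenotype 'y' must be coded 0/1")
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("genotype score 'x' must be finite numeric")
  if (!is.null(x2) && (!is.numeric(x2) || any(!is.finite(x2))))
    stop("genotype indicator 'x2' must be finite numeric")
  d <- data.frame(y = as.integer(y), x = as.numeric(x), z = factor(z))
  if (!is.null(x2)) d$x2 <- as.numeric(x2)
  class(d) <- c("cc_data", "data.frame")
  d
}

#' Read stratified case-control data from delimited text
#'
#' Expects a header with columns `y`, `z` and either `x` or the pair
#' `x1`, `x2` (two genotype indicators). Rows with missing values in the used
#' columns are dropped; the number dropped is recorded in attribute
#' `"n_dropped"` and reported via [message()].
#'
#' @param path Path to a TSV or CSV file (separator chosen by extension, or
#'   give `sep`).
#' @param sep Field separator; default `"\t"` unless the file ends in `.csv`.
#' @return A `"cc_data"` data frame.
#' @export
read_cc_data <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("y", "z")
  for (col in need)
    if (!col %in% names(raw)) stop("missing required column '", col, "' in ", path)
  two_df <- all(c("x1", "x2") %in% names(raw))
  if (!two_df && !"x" %in% names(raw))
    stop("missing required column 'x' (or pair 'x1','x2') in ", path)
  use <- if (two_df) c("y", "z", "x1", "x2") else c("y", "z", "x")
  keep <- stats::complete.cases(raw[use])
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_cc_data: dropped ", n_dropped, " row(s) with missing values")
  raw <- raw[keep, use, drop = FALSE]
  if (!all(raw$y %in% c(0, 1)))
    stop("phenotype column 'y' must contain only 0 and 1")
  d <- if (two_df) cc_data(raw$y, raw$x1, raw$z, x2 = raw$x2)
       else cc_data(raw$y, raw$x, raw$z)
  attr(d, "n_dropped") <- n_dropped
  d
}

#' Per-stratum weight schemes
#'
#' A weight scheme attaches one positive weight to each stratum of a
#' [cc_data()] object. `unit_weights()` gives the classical unweighted
#' (Cochran-Armitage / Mantel) tests. `estimate_weights()` derives weights
#' from an assumed population link function, evaluating [cc_weight()] at each
#' stratum's observed case fraction: for power-odds links the sampling ratio
#' `K` affects all weights only through a common factor and may be left at 1;
#' for other links an (approximate) `K` should be supplied. Weights are
#' reported unnormalized; all tests are invariant to a global rescaling.
#'
#' @param data A `"cc_data"` object.
#' @param link A `"link_spec"` or link name.
#' @param K Assumed ratio of case to non-case sampling fractions.
#' @param w Named numeric vector of per-stratum weights (names are stratum
#'   levels).
#' @param provenance Short description of how the weights arose.
#' @return An object of class `"weight_scheme"`.
#' @export
weight_scheme <- function(w, provenance = "custom") {
  if (!is.numeric(w) || any(!is.finite(w)) || any(w <= 0))
    stop("weights must be finite and positive")
  if (is.null(names(w))) stop("weights must be named by stratum level")
  structure(list(w = w, provenance = provenance), class = "weight_scheme")
}

#' @rdname weight_scheme
#' @export
unit_weights <- function(data) {
  lev <- levels(data$z)
  weight_scheme(stats::setNames(rep(1, length(lev)), lev), provenance = "unit")
}

#' @rdname weight_scheme
#' @export
estimate_weights <- function(data, link, K = 1) {
  link <- as_link(link)
  lev <- levels(data$z)
  mu <- vapply(split(data$y, data$z), mean, numeric(1))
  # degenerate strata (all cases or all controls) contribute nothing to the
  # tests; give them a finite weight by pulling mu off the boundary
  n_z <- vapply(split(data$y, data$z), length, numeric(1))
  mu <- pmin(pmax(mu, 1 / (2 * n_z + 2)), 1 - 1 / (2 * n_z + 2))
  prov <- if (is.null(link$lambda)) link$name
          else sprintf("%s(lambda=%g)", link$name, link$lambda)
  weight_scheme(stats::setNames(cc_weight(link, mu, K), lev),
                provenance = sprintf("%s, K=%g", prov, K))
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Stratum weights (", x$provenance, "):\n", sep = "")
  print(round(x$w, 4))
  invisible(x)
}

resolve_weights <- function(data, weights) {
  if (inherits(weights, "weight_scheme")) w <- weights$w
  else if (is.numeric(weights)) w <- weights
  else if (inherits(weights, "link_spec") || is.character(weights))
    w <- estimate_weights(data, weights)$w
  else stop("'weights' must be a weight_scheme, a named numeric vector, or a link")
  lev <- levels(data$z)
  if (is.null(names(w))) {
    if (length(w) != length(lev))
      stop("unnamed weight vector must have one entry per stratum")
    names(w) <- lev
  }
  missing <- setdiff(lev, names(w))
  if (length(missing))
    stop("no weight defined for stratum/strata: ", paste(missing, collapse = ", "))
  w[lev]
}
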