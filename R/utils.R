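# Run code with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# biased (divide-by-n) sample variance / covariance
s2 <- function(v) mean((v - mean(v))^2)
cov_biased <- function(m) {
  mc <- sweep(m, 2, colMeans(m))
  crossprod(mc) / nrow(m)
}
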