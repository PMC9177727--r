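# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG seed, restoring the caller's
# RNG state afterwards (so package functions never perturb the
# global random stream).
withSeed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# log2 odds of a proportion; p in {0, 1} maps to -Inf / Inf.
log2Odds <- function(p) log2(p) - log2(1 - p)

# Beta-Binomial draws parameterized by mean p and overdispersion
# rho in [0, 1); rho = 0 degenerates to the Binomial.
rbetabinom <- function(n, size, p, rho = 0) {
  stopifnot(rho >= 0, rho < 1, all(p > 0 & p < 1))
  if (rho == 0) return(stats::rbinom(n, size, p))
  nu <- (1 - rho) / rho           # a + b
  pr <- stats::rbeta(n, p * nu, (1 - p) * nu)
  stats::rbinom(n, size, pr)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
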