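test_that("conjugate posterior and MAP transform match analytic values", {
  p <- allelePosterior(50, 50)
  expect_equal(unname(p), c(51, 51))
  est <- logRatioEstimate(p)
  expect_equal(est$map, 0)
  expect_equal(est$call, "balanced")
  # mode (a-1)/(a+b-2) = 0.75 -> log2(3)
  est2 <- logRatioEstimate(allelePosterior(75, 25))
  expect_equal(est2$map, log2(3))
  expect_equal(est2$call, "mutant")
  # boundary: zero mutant reads -> -Inf MAP, finite CI, classification by CI
  est0 <- logRatioEstimate(allelePosterior(0, 30))
  expect_identical(est0$map, -Inf)
  expect_true(is.finite(est0$lo) && is.finite(est0$hi))
  expect_equal(est0$call, "wildtype")
  expect_error(allelePosterior(0, 0), "zero")
})

test_that("credible bounds match brute-force density integration", {
  # independent oracle: invert the Beta CDF by numerical integration
  oracleQuantile <- function(target, a, b) {
    stats::uniroot(function(p) {
      stats::integrate(function(u) stats::dbeta(u, a, b), 0, p,
                       rel.tol = 1e-12)$value - target
    }, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  set.seed(11)
  pairs <- cbind(mut = sample(0:120, 20), wt = sample(1:120, 20))
  for (i in seq_len(nrow(pairs))) {
    post <- allelePosterior(pairs[i, "mut"], pairs[i, "wt"])
    est <- logRatioEstimate(post)
    lo_p <- oracleQuantile(0.055, post[["shape1"]], post[["shape2"]])
    hi_p <- oracleQuantile(0.945, post[["shape1"]], post[["shape2"]])
    expect_equal(est$lo, log2(lo_p / (1 - lo_p)), tolerance = 1e-6)
    expect_equal(est$hi, log2(hi_p / (1 - hi_p)), tolerance = 1e-6)
  }
})

test_that("alpha MAP is monotone in mutant reads at fixed wild-type depth", {
  maps <- vapply(0:80, function(m) logRatioEstimate(allelePosterior(m, 40))$map,
                 numeric(1))
  expect_true(all(diff(maps) >= 0))
})

test_that("gamma MAP is the difference of component MAPs with Monte-Carlo CI", {
  spec <- posteriorSpec(seed = 42)
  same <- gammaEstimate(allelePosterior(50, 50), allelePosterior(50, 50), spec)
  expect_equal(same$map, 0)
  expect_equal(same$call, "balanced")
  g <- gammaEstimate(allelePosterior(80, 20), allelePosterior(50, 50), spec)
  expect_equal(g$map, 2)                       # log2(4): difference of modes
  expect_lt(abs(mean(c(g$lo, g$hi)) - 2), 0.2) # CI brackets the MAP
  # determinism under a fixed seed
  g2 <- gammaEstimate(allelePosterior(80, 20), allelePosterior(50, 50), spec)
  expect_identical(g, g2)
  # draws floor enforced
  expect_error(gammaEstimate(allelePosterior(8, 2), allelePosterior(5, 5),
                             posteriorSpec(nDraws = 100)), "nDraws")
})

test_that("gamma Monte-Carlo interval is converged at the default draw count", {
  # doubling the draws moves the CI endpoints by < 0.02 log2 units
  for (counts in list(c(20, 10, 18, 12), c(60, 40, 45, 55))) {
    a <- allelePosterior(counts[1], counts[2])
    b <- allelePosterior(counts[3], counts[4])
    g1 <- gammaEstimate(a, b, posteriorSpec(nDraws = 2e4, seed = 7))
    g2 <- gammaEstimate(a, b, posteriorSpec(nDraws = 4e4, seed = 8))
    expect_lt(abs(g1$lo - g2$lo), 0.02)
    expect_lt(abs(g1$hi - g2$hi), 0.02)
  }
})

test_that("per-sample profiles carry consistent sign logic", {
  # counts given as (mut, wt): copy-number loss of the mutant allele but
  # preferential expression of it
  p <- profileSample(dnaMut = 30, dnaWt = 70, rnaMut = 70, rnaWt = 30)
  expect_equal(p$beta_call, "wildtype")
  expect_equal(p$alpha_call, "mutant")
  expect_equal(p$gamma_call, "mutant")
  expect_equal(p$gamma_map, p$alpha_map - p$beta_map)
  balanced <- profileSample(50, 50, 50, 50)
  expect_equal(unname(unlist(balanced[, c("alpha_call", "beta_call", "gamma_call")])),
               rep("balanced", 3))
  same_ratio <- profileSample(10, 20, 10, 20)
  expect_equal(same_ratio$gamma_call, "balanced")
  expect_equal(same_ratio$gamma_map, 0)
})

test_that("cohort profiling is reproducible and order-invariant", {
  sim <- simulateCohort(simulationConfig(nSamples = 12, seed = 3))
  pr1 <- profileCohort(sim$counts, posteriorSpec(seed = 5))
  pr2 <- profileCohort(sim$counts, posteriorSpec(seed = 5))
  expect_identical(as.data.frame(pr1), as.data.frame(pr2))
  shuffled <- AllelicCounts(as.data.frame(sim$counts)[rev(seq_len(nrow(sim$counts))), ])
  pr3 <- profileCohort(shuffled, posteriorSpec(seed = 5))
  expect_identical(as.data.frame(pr1), as.data.frame(pr3))
  expect_true(all(pr1$gamma_lo <= pr1$gamma_hi))
  expect_true(all(pr1$alpha_lo <= pr1$alpha_map & pr1$alpha_map <= pr1$alpha_hi))
})

test_that("imbalance calls obey the CI-versus-zero rule", {
  sim <- simulateCohort(simulationConfig(nSamples = 30, seed = 9))
  pr <- profileCohort(sim$counts)
  for (kind in c("alpha", "beta", "gamma")) {
    lo <- pr[[paste0(kind, "_lo")]]; hi <- pr[[paste0(kind, "_hi")]]
    call <- pr[[paste0(kind, "_call")]]
    expect_equal(call == "balanced", lo <= 0 & hi >= 0)
    expect_equal(call == "mutant", lo > 0)
    expect_equal(call == "wildtype", hi < 0)
  }
})
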