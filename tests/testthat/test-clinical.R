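test_that("gamma categorization is a pure mapping of the CI call", {
  profiles <- data.frame(
    sample_id = c("A", "B", "C", "D"),
    gamma_lo = c(0.2, -1.0, -0.3, NA),
    gamma_hi = c(1.4, -0.1, 0.3, NA),
    gamma_call = c("mutant", "wildtype", "balanced", NA))
  cats <- categorizeGamma(profiles)
  expect_equal(cats$category,
               c("gamma_mut", "gamma_wt", "gamma_balanced"))
  dropped <- attr(cats, "dropped")
  expect_equal(dropped$sample_id, "D")
  expect_equal(dropped$reason, "missing_gamma_call")
  # permutation invariance
  cats_rev <- categorizeGamma(profiles[3:1, ])
  expect_equal(cats_rev$category[order(cats_rev$sample_id)],
               cats$category[order(cats$sample_id)])
})

test_that("group comparisons dispatch Wilcoxon/Kruskal-Wallis and detect shifts", {
  same <- groupComparison(rep(c(1, 2, 3, 4), 2), rep(c("x", "y"), each = 4))
  expect_equal(same$method, "wilcoxon")
  expect_gt(same$p_value, 0.8)
  three <- groupComparison(stats::rnorm(30), rep(c("LumA", "LumB", "Basal"), 10))
  expect_equal(three$method, "kruskal-wallis")
  expect_error(groupComparison(1:4, rep("only", 4)), "at least 2 groups")
  # power: gamma shifted +1 log2 in the receptor-negative arm, 40 per arm
  hits <- vapply(1:20, function(s) {
    set.seed(200 + s)
    v <- c(stats::rnorm(40, 0, 0.6), stats::rnorm(40, 1, 0.6))
    groupComparison(v, rep(c("positive", "negative"), each = 40))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("covariate associations apply per-study BH adjustment", {
  set.seed(5)
  n <- 60
  profiles <- data.frame(
    sample_id = sprintf("S%02d", 1:n),
    gamma_map = c(stats::rnorm(n / 2, 0, 0.5), stats::rnorm(n / 2, 1.2, 0.5)))
  clinical <- data.frame(
    sample_id = profiles$sample_id,
    er_status = rep(c("positive", "negative"), each = n / 2),
    noise_cov = sample(c("g1", "g2"), n, replace = TRUE))
  res <- clinicalAssociations(profiles, clinical,
                              c("er_status", "noise_cov"))
  expect_equal(nrow(res), 2L)
  expect_true(res$significant[res$covariate == "er_status"])
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"))
})

test_that("Kaplan-Meier machinery handles identical, separated and event-free groups", {
  t0 <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e0 <- c(1, 1, 0, 1, 1, 0, 1, 1)
  ident <- kmLogrank(rep(t0, 2), rep(e0, 2),
                     rep(c("gamma_mut", "gamma_balanced"), each = 8))
  expect_gt(ident$logrank_p, 0.99)
  # exponential hazards differing twofold, 100 per group
  hits <- vapply(1:20, function(s) {
    set.seed(300 + s)
    tt <- c(stats::rexp(100, 0.2), stats::rexp(100, 0.1))
    cc <- stats::runif(200, 0, 25)
    km <- kmLogrank(pmin(tt, cc), as.integer(tt <= cc),
                    rep(c("gamma_mut", "gamma_balanced"), each = 100))
    km$logrank_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # all censored: no events, undefined medians, no test
  cens <- kmLogrank(t0, rep(0, 8), rep(c("a", "b"), each = 4))
  expect_true(all(is.na(cens$medians)))
  expect_true(is.na(cens$logrank_p))
  expect_equal(unname(cens$n_events), c(0, 0))
})

test_that("log-rank P is invariant to group relabeling", {
  set.seed(9)
  tt <- stats::rexp(60, 0.15); ev <- stats::rbinom(60, 1, 0.7)
  g <- rep(c("gamma_mut", "gamma_balanced", "gamma_wt"), each = 20)
  p1 <- kmLogrank(tt, ev, g)$logrank_p
  relabel <- c(gamma_mut = "grp1", gamma_balanced = "grp2", gamma_wt = "grp3")
  p2 <- kmLogrank(tt, ev, unname(relabel[g]))$logrank_p
  expect_equal(p1, p2)
})

test_that("Cox model recovers a known hazard ratio and flags bad inputs", {
  recovered <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 500
    grp <- rep(c("gamma_balanced", "gamma_mut"), each = n / 2)
    hz <- ifelse(grp == "gamma_mut", 0.2, 0.1)
    tt <- stats::rexp(n, hz); cc <- stats::runif(n, 0, 25)
    d <- data.frame(os_time = pmin(tt, cc), os_event = as.integer(tt <= cc),
                    category = grp)
    fit <- coxMultivariate(d)
    fit$hr[fit$term == "categorygamma_mut"]
  }, numeric(1))
  expect_gte(mean(recovered >= 1.6 & recovered <= 2.5), 0.9)
  # null covariate: the 95% CI covers 1 most of the time
  covered <- vapply(1:20, function(s) {
    set.seed(500 + s)
    n <- 200
    d <- data.frame(os_time = stats::rexp(n, 0.15),
                    os_event = stats::rbinom(n, 1, 0.8),
                    category = sample(c("gamma_balanced", "gamma_mut"), n,
                                      replace = TRUE),
                    null_cov = stats::rnorm(n))
    fit <- coxMultivariate(d, covariates = "null_cov")
    row <- fit[fit$term == "null_cov", ]
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.8)
  d_const <- data.frame(os_time = stats::rexp(40, 0.2),
                        os_event = rep(1L, 40),
                        category = rep(c("gamma_balanced", "gamma_mut"), 20),
                        flat = 1)
  expect_error(coxMultivariate(d_const, covariates = "flat"), "constant")
})
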