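test_that("variant filter applies the intensity and heterozygosity rules", {
  gt <- rbind(gtRow(6, 4), gtRow(6, 4), gtRow(4, 6), gtRow(5, 5))
  rownames(gt) <- c("pass", "edge_intensity", "few_het", "pass2")
  x <- makeAEMatrix(gt, intensity = c(10.2, 9.5, 11, 9.6))
  f <- filterVariants(x)
  expect_setequal(rownames(f), c("pass", "pass2"))
  excl <- S4Vectors::metadata(f)$excluded_variants
  expect_equal(excl$reason[excl$variant_id == "edge_intensity"],
               "low_intensity")   # 9.5 exactly fails the strict cutoff
  expect_equal(excl$reason[excl$variant_id == "few_het"], "few_heterozygotes")
})

test_that("AE ratios are defined at heterozygotes and antisymmetric in allele labels", {
  gt <- rbind(v1 = gtRow(3, 2, 2))
  ae_true <- matrix(c(0.9, -0.3, 0.58, 0, 0, 0, 0), 1)
  x <- makeAEMatrix(gt, aeTrue = ae_true)
  ae <- aeRatio(x)
  expect_equal(unname(ae[1, 1:3]), c(0.9, -0.3, 0.58))
  expect_true(all(is.na(ae[1, 4:7])))       # homozygotes undefined
  # swapping allele labels A<->B flips both log ratios and the genotypes
  gt_swapped <- gt
  gt_swapped[gt == "AA"] <- "BB"; gt_swapped[gt == "BB"] <- "AA"
  x_swapped <- AEMatrix(-SummarizedExperiment::assay(x, "rnaLogRatio"),
                        -SummarizedExperiment::assay(x, "dnaLogRatio"),
                        gt_swapped,
                        data.frame(variant_id = "v1", chrom = "chr3",
                                   pos = 100L, allele_a = "C", allele_b = "T"),
                        11)
  expect_equal(aeRatio(x_swapped), -ae)
})

test_that("heterozygote-vs-homozygote t test matches the textbook oracle", {
  het <- c(1.2, 1.0, 1.4, -1.1, -1.3)
  hom <- c(0.0, 0.1, -0.1, 0.05)
  gt <- rbind(v1 = gtRow(5, 2, 2), v2 = gtRow(1, 8))
  x <- makeAEMatrix(gt)
  rna <- SummarizedExperiment::assay(x, "rnaLogRatio")
  rna[1, ] <- c(het, hom)
  x <- AEMatrix(rna, SummarizedExperiment::assay(x, "dnaLogRatio"),
                gt, data.frame(variant_id = c("v1", "v2"), chrom = "chr3",
                               pos = c(100L, 200L), allele_a = "A",
                               allele_b = "C"), c(11, 11))
  res <- hetVsHomTest(x)
  # Welch statistic computed from first principles
  m1 <- mean(het); m2 <- mean(hom)
  se <- sqrt(var(het) / 5 + var(hom) / 4)
  df <- se^4 / ((var(het) / 5)^2 / 4 + (var(hom) / 4)^2 / 3)
  p_oracle <- 2 * stats::pt(abs((m1 - m2) / se), df, lower.tail = FALSE)
  expect_equal(res$p_value[1], p_oracle, tolerance = 1e-12)
  # a single het sample cannot be tested
  expect_equal(res$skipped_reason[2], "group_too_small")
})

test_that("DAE calling is inclusive at the threshold and applies the daeSNP rule", {
  # 10 hets, 3 at or above 0.58 (one exactly at it) -> daeSNP
  ae1 <- c(0.58, 0.7, -0.9, rep(0.1, 7))
  # 40 hets, 3 above threshold -> 7.5% < 10%, not a daeSNP
  ae2 <- c(0.9, 0.8, -0.7, rep(0.05, 37))
  gt <- rbind(v1 = c(gtRow(10, 15, 15)), v2 = gtRow(40, 0, 0))
  x <- makeAEMatrix(gt, aeTrue = rbind(c(ae1, rep(0, 30)), ae2))
  res <- callDAE(x)
  expect_equal(res$n_het, c(10L, 40L))
  expect_equal(res$n_dae, c(3L, 3L))
  expect_equal(res$is_daesnp, c(TRUE, FALSE))
  # raising the threshold never increases the DAE count
  thresholds <- c(0.3, 0.58, 0.8, 1.0)
  n_dae <- vapply(thresholds, function(th) callDAE(x, threshold = th)$n_dae[1],
                  integer(1))
  expect_true(all(diff(n_dae) <= 0))
})

test_that("mapping P for complete separation matches exhaustive rank enumeration", {
  # |AE| at the daeSNP: het group {0.9, 1.1, 1.0} vs hom {0.1, 0.2, 0.0}
  gt <- rbind(dae = gtRow(6, 0),
              cand = c(rep("AB", 3), "AA", "AA", "BB"))
  ae <- rbind(c(0.9, 1.1, 1.0, 0.1, 0.2, 0.0), rep(0, 6))
  x <- makeAEMatrix(gt, aeTrue = ae, pos = c(1000000L, 1010000L))
  res <- daeMapping(x, "dae")
  # brute-force: over all C(6,3) het/hom label assignments, how often is
  # the het rank sum at least as large as observed?
  vals <- c(0.9, 1.1, 1.0, 0.1, 0.2, 0.0)
  obs <- sum(rank(vals)[1:3])
  sums <- utils::combn(6, 3, function(i) sum(rank(vals)[i]))
  p_oracle <- mean(sums >= obs)              # = 1/20
  expect_equal(res$p_value[res$candidate_snp_id == "cand"], p_oracle)
  expect_equal(p_oracle, 1 / choose(6, 3))
})

test_that("mapping window is inclusive at 250 kb and groups need 2 samples", {
  gt <- rbind(dae = gtRow(6, 2),
              edge_in = gtRow(4, 4), edge_out = gtRow(4, 4),
              small = c(rep("AB", 1), rep("AA", 7)))
  pos <- c(1000000L, 1250000L, 1250001L, 1100000L)
  set.seed(2)
  x <- makeAEMatrix(gt, aeTrue = rbind(stats::runif(8, 0, 1), 0, 0, 0),
                    pos = pos)
  res <- daeMapping(x, "dae")
  expect_setequal(res$candidate_snp_id, c("edge_in", "small"))
  expect_equal(res$skipped_reason[res$candidate_snp_id == "small"],
               "group_too_small")
})

test_that("BH q values are rank-monotone and no stricter than Bonferroni", {
  sim <- simulateMicroarray(nVariants = 14, seed = 17)
  res <- daeMapping(sim$ae, sim$truth$daesnp_id)
  res <- res[!is.na(res$p_value), ]
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))
  bonf <- stats::p.adjust(res$p_value, method = "bonferroni") <= 0.05
  expect_true(all(which(bonf) %in% which(res$q_value <= 0.05)))
})

test_that("eQTL test dispatches by group count and detects shifts", {
  set.seed(6)
  e <- stats::rnorm(60)
  g <- rep(c("AA", "AB", "BB"), each = 20)
  null_res <- eqtlTest(rep(rep(1:5, 4), 3), rep(c("AA", "AB", "BB"), each = 20))
  expect_equal(null_res$method, "kruskal-wallis")
  expect_gt(null_res$p_value, 0.99)          # identical group distributions
  two <- eqtlTest(e[1:40], g[1:40])
  expect_equal(two$method, "wilcoxon")
  expect_error(eqtlTest(e[1:20], g[1:20]), "at least 2")
  # power: 1-SD shift per genotype group, 30 per group
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    expr <- stats::rnorm(90) + rep(c(0, 1, 2), each = 30)
    eqtlTest(expr, rep(c("AA", "AB", "BB"), each = 30))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("planted regulatory structure is recovered from simulated arrays", {
  sim <- simulateMicroarray(nVariants = 16, nSamples = 64,
                            daesnpEffect = 1.0, ldR2 = 0.8, seed = 23)
  f <- filterVariants(sim$ae)
  dae <- callDAE(f)
  expect_true(dae$is_daesnp[dae$variant_id == sim$truth$daesnp_id])
  mp <- daeMapping(f, sim$truth$daesnp_id)
  rsnp_q <- mp$q_value[mp$candidate_snp_id == sim$truth$rsnp_id]
  expect_lte(rsnp_q, 0.05)
})
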