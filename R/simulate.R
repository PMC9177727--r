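#' SimulationConfig: tumor-cohort generator settings
#'
#' Parameters of the synthetic tumor cohort generator. Defaults
#' emulate a breast-tumor cohort of 94 samples carrying one
#' heterozygous somatic missense mutation each, with overdispersed
#' sequencing depths, a copy-number skew in a subset of tumors, a
#' mutant-skewed cis-regulatory effect in a minority, bulk-tissue
#' cellularity attenuating the RNA-side effect, and clinical labels
#' plus survival times linked to the true cis effect.
#'
#' @slot nSamples number of tumors.
#' @slot depthDna,depthRna mean sequencing depths (negative-binomial
#'   distributed per sample, dispersion size 20).
#' @slot pCnImbalance fraction of tumors with a copy-number skew.
#' @slot cnLogoddsSd spread (log2 odds) of true beta values among
#'   skewed tumors (mean zero).
#' @slot pCisEffect fraction of tumors with a cis-regulatory effect.
#' @slot cisLogoddsMean,cisLogoddsSd location/spread (log2 odds) of
#'   true gamma values among affected tumors; a positive mean gives
#'   the mutant-preferring skew.
#' @slot rho Beta-Binomial overdispersion of read counts in [0, 1).
#' @slot cellularityRange range of per-tumor cellularity; cellularity
#'   multiplies the cis effect on the RNA side.
#' @slot hrGammaMut hazard ratio of death for tumors with a true
#'   mutant-preferring cis effect, relative to the rest.
#' @slot seed integer seed; generation is byte-reproducible.
#' @seealso [simulationConfig()], [simulateCohort()]
#' @export
setClass("SimulationConfig",
         representation(nSamples = "integer", depthDna = "numeric",
                        depthRna = "numeric", pCnImbalance = "numeric",
                        cnLogoddsSd = "numeric", pCisEffect = "numeric",
                        cisLogoddsMean = "numeric", cisLogoddsSd = "numeric",
                        rho = "numeric", cellularityRange = "numeric",
                        hrGammaMut = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@nSamples < 1) msg <- c(msg, "nSamples must be positive")
  for (p in c(object@pCnImbalance, object@pCisEffect))
    if (p < 0 || p > 1) msg <- c(msg, "probabilities must lie in [0, 1]")
  if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho must be in [0, 1)")
  if (length(object@cellularityRange) != 2 ||
      any(object@cellularityRange < 0 | object@cellularityRange > 1) ||
      diff(object@cellularityRange) < 0)
    msg <- c(msg, "cellularityRange must be an interval within [0, 1]")
  if (object@depthDna < 30 || object@depthRna < 30)
    msg <- c(msg, "mean depths below 30 cannot satisfy the depth filter")
  if (object@hrGammaMut <= 0) msg <- c(msg, "hrGammaMut must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SimulationConfig
#'
#' @param nSamples,depthDna,depthRna,pCnImbalance,cnLogoddsSd
#'   see [SimulationConfig-class].
#' @param pCisEffect,cisLogoddsMean,cisLogoddsSd,rho,cellularityRange
#'   see [SimulationConfig-class].
#' @param hrGammaMut,seed see [SimulationConfig-class].
#' @return a `SimulationConfig` object.
#' @examples
#' simulationConfig(nSamples = 50, seed = 1)
#' @export
simulationConfig <- function(nSamples = 94L, depthDna = 100, depthRna = 100,
                             pCnImbalance = 0.7, cnLogoddsSd = 0.8,
                             pCisEffect = 0.3, cisLogoddsMean = 0.8,
                             cisLogoddsSd = 0.4, rho = 0.01,
                             cellularityRange = c(0.6, 1),
                             hrGammaMut = 2.1, seed = 20220608L) {
  new("SimulationConfig", nSamples = as.integer(nSamples),
      depthDna = depthDna, depthRna = depthRna,
      pCnImbalance = pCnImbalance, cnLogoddsSd = cnLogoddsSd,
      pCisEffect = pCisEffect, cisLogoddsMean = cisLogoddsMean,
      cisLogoddsSd = cisLogoddsSd, rho = rho,
      cellularityRange = cellularityRange, hrGammaMut = hrGammaMut,
      seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0("SimulationConfig: %d samples, depths %g/%g (DNA/RNA), ",
                     "P(CN skew) %.2f, P(cis) %.2f, seed %d\n"),
              object@nSamples, object@depthDna, object@depthRna,
              object@pCnImbalance, object@pCisEffect, object@seed))
})

#' Simulate a tumor cohort with known allelic-imbalance structure
#'
#' Generates, per tumor: a true copy-number log2-odds skew `beta0`
#' (zero in unaffected tumors), a true cis-regulatory log2-odds
#' effect `gamma0`, a cellularity that attenuates the cis effect in
#' the bulk RNA signal (`gamma_eff = gamma0 * cellularity`),
#' Beta-Binomial DNA read counts at allelic fraction
#' `logistic(beta0 * ln 2)` and RNA counts at
#' `logistic((beta0 + gamma_eff) * ln 2)`, hormone-receptor labels
#' whose negativity probability increases with `gamma_eff`, and
#' exponential survival times whose hazard is multiplied by
#' `hrGammaMut` for tumors with a true mutant-preferring cis effect.
#'
#' @param config a [SimulationConfig-class].
#' @return a list with `counts` (an [AllelicCounts-class], DNA and RNA
#'   records at one missense locus per tumor), `truth` (a
#'   `data.frame`: `sample_id`, `beta0`, `gamma0`, `cellularity`,
#'   `gamma_eff`, `cis_affected`, `cn_affected`), and `clinical`
#'   (a `data.frame` in the [readClinical()] schema).
#' @examples
#' sim <- simulateCohort(simulationConfig(nSamples = 20, seed = 7))
#' head(sim$truth)
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopIfNot(is(config, "SimulationConfig"), "config must be a SimulationConfig")
  n <- config@nSamples
  withSeed(config@seed, {
    sample_id <- sprintf("S%03d", seq_len(n))
    cn_affected <- stats::runif(n) < config@pCnImbalance
    beta0 <- ifelse(cn_affected, stats::rnorm(n, 0, config@cnLogoddsSd), 0)
    cis_affected <- stats::runif(n) < config@pCisEffect
    gamma0 <- ifelse(cis_affected,
                     stats::rnorm(n, config@cisLogoddsMean, config@cisLogoddsSd),
                     0)
    cellularity <- stats::runif(n, config@cellularityRange[1],
                                config@cellularityRange[2])
    gamma_eff <- gamma0 * cellularity
    depth_dna <- stats::rnbinom(n, mu = config@depthDna, size = 20)
    depth_rna <- stats::rnbinom(n, mu = config@depthRna, size = 20)
    p_dna <- stats::plogis(beta0 * log(2))
    p_rna <- stats::plogis((beta0 + gamma_eff) * log(2))
    mut_dna <- rbetabinom(n, depth_dna, p_dna, config@rho)
    mut_rna <- rbetabinom(n, depth_rna, p_rna, config@rho)
    counts <- AllelicCounts(data.frame(
      sample_id = rep(sample_id, 2),
      chrom = "chr3", pos = 178936091L,
      assay = rep(c("DNA", "RNA"), each = n),
      wt_reads = c(depth_dna - mut_dna, depth_rna - mut_rna),
      mut_reads = c(mut_dna, mut_rna),
      mutation_class = "missense", stringsAsFactors = FALSE))
    truth <- data.frame(sample_id = sample_id, beta0 = beta0, gamma0 = gamma0,
                        cellularity = cellularity, gamma_eff = gamma_eff,
                        cis_affected = cis_affected, cn_affected = cn_affected,
                        stringsAsFactors = FALSE)
    # clinical labels: receptor negativity more likely with higher gamma_eff
    p_er_neg <- stats::plogis(stats::qlogis(0.25) + 0.6 * gamma_eff)
    p_pr_neg <- stats::plogis(stats::qlogis(0.35) + 0.6 * gamma_eff)
    p_her2_pos <- stats::plogis(stats::qlogis(0.15) + 0.5 * gamma_eff)
    toStatus <- function(neg) ifelse(neg, "negative", "positive")
    gamma_mut_true <- cis_affected & gamma0 > 0
    base_hazard <- log(2) / 12.5          # balanced-group median ~12.5 years
    hazard <- base_hazard * ifelse(gamma_mut_true, config@hrGammaMut, 1)
    t_death <- stats::rexp(n, hazard)
    t_cens <- stats::runif(n, 2, 30)
    os_time <- pmin(t_death, t_cens)
    os_event <- as.integer(t_death <= t_cens)
    # disease-specific deaths: a fraction of deaths are from other causes
    disease_death <- os_event == 1 & stats::runif(n) < 0.8
    clinical <- data.frame(
      sample_id = sample_id,
      age = round(stats::rnorm(n, 61, 12), 1),
      er_status = toStatus(stats::runif(n) < p_er_neg),
      pr_status = toStatus(stats::runif(n) < p_pr_neg),
      her2_status = ifelse(stats::runif(n) < p_her2_pos, "positive", "negative"),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.45, 0.35)),
      size = round(stats::rlnorm(n, log(2.2), 0.45), 2),
      stage = sample(1:3, n, replace = TRUE, prob = c(0.35, 0.5, 0.15)),
      pam50 = sample(c("LumA", "LumB", "Her2", "Basal"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.1, 0.1)),
      os_time = round(os_time, 3), os_event = os_event,
      dss_time = round(os_time, 3),
      dss_event = as.integer(disease_death),
      stringsAsFactors = FALSE)
    list(counts = counts, truth = truth, clinical = clinical)
  })
}

#' Simulate a normal-tissue microarray allelic-expression panel
#'
#' Builds an [AEMatrix-class] containing one planted daeSNP, one
#' regulatory variant (rSNP) in incomplete linkage disequilibrium
#' with it, and a set of null candidate variants. Haplotypes for the
#' rSNP/daeSNP pair are drawn at the requested LD (`r = sqrt(ldR2)`),
#' and the haplotype carrying the rSNP up-allele expresses more, so
#' samples heterozygous at the rSNP show an AE shift at the daeSNP
#' whose sign follows the phase (strong LD gives a unilateral AE
#' distribution, weak LD a bilateral one). Homozygous array log
#' ratios sit at large absolute values as on real genotyping arrays.
#'
#' @param nVariants total number of variants (>= 3: daeSNP, rSNP and
#'   null candidates).
#' @param nSamples number of individuals (default 64).
#' @param daesnpEffect AE shift (log2) per copy of the rSNP up-allele
#'   difference between haplotypes.
#' @param ldR2 squared LD between rSNP and daeSNP, in [0, 1].
#' @param mafRsnp,mafDaesnp allele frequencies of the rSNP up-allele
#'   and the daeSNP B allele.
#' @param noiseSd measurement noise of the array log ratios (log2).
#' @param seed integer seed.
#' @return a list with `ae` (an [AEMatrix-class]; the planted daeSNP
#'   is `"daeSNP_1"` and the regulatory variant `"rSNP_1"`) and
#'   `truth` (list: `daesnp_id`, `rsnp_id`, `effect`, `ld_r2`,
#'   `rsnp_genotype`).
#' @examples
#' sim <- simulateMicroarray(nVariants = 10, seed = 3)
#' sim$ae
#' @export
simulateMicroarray <- function(nVariants = 20, nSamples = 64,
                               daesnpEffect = 1.0, ldR2 = 0.8,
                               mafRsnp = 0.35, mafDaesnp = 0.35,
                               noiseSd = 0.15, seed = 20220608L) {
  stopIfNot(ldR2 >= 0 && ldR2 <= 1, "ldR2 must lie in [0, 1]")
  stopIfNot(nVariants >= 3, "need at least 3 variants")
  withSeed(seed, {
    r <- sqrt(ldR2)
    pA <- mafRsnp; pB <- mafDaesnp
    D <- r * sqrt(pA * (1 - pA) * pB * (1 - pB))
    hap_freq <- c(`11` = pA * pB + D, `10` = pA * (1 - pB) - D,
                  `01` = (1 - pA) * pB - D, `00` = (1 - pA) * (1 - pB) + D)
    stopIfNot(all(hap_freq >= -1e-12), "infeasible LD for these frequencies")
    hap_freq <- pmax(hap_freq, 0)
    haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), ncol = 2, byrow = TRUE)
    draw <- function() haps[sample.int(4, 2, replace = TRUE,
                                       prob = hap_freq), , drop = FALSE]
    hap_list <- replicate(nSamples, draw(), simplify = FALSE)
    rsnp_dose <- vapply(hap_list, function(h) sum(h[, 1]), numeric(1))
    dae_dose <- vapply(hap_list, function(h) sum(h[, 2]), numeric(1))
    doseToGt <- function(d) c("AA", "AB", "BB")[d + 1]   # B = "1" allele
    n_null <- nVariants - 2L
    ids <- c("daeSNP_1", "rSNP_1",
             if (n_null) sprintf("snp_%02d", seq_len(n_null)))
    pos0 <- 178900000L
    null_pos <- if (n_null) pos0 + as.integer(round(seq(-200000, 200000,
                                                        length.out = n_null)))
                else integer(0)
    variants <- data.frame(
      variant_id = ids, chrom = "chr3",
      pos = c(pos0, pos0 + 50000L, null_pos),
      allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
    gt <- matrix(NA_character_, nVariants, nSamples,
                 dimnames = list(ids, sprintf("N%03d", seq_len(nSamples))))
    gt["daeSNP_1", ] <- doseToGt(dae_dose)
    gt["rSNP_1", ] <- doseToGt(rsnp_dose)
    for (k in seq_len(n_null)) {
      maf <- stats::runif(1, 0.2, 0.5)
      gt[ids[2L + k], ] <- doseToGt(stats::rbinom(nSamples, 2, maf))
    }
    # true AE at the daeSNP: expression boost on haplotypes carrying the
    # rSNP up-allele; ratio is allele A over allele B of the daeSNP
    aeTrueAt <- function(h) {
      if (sum(h[, 2]) != 1) return(0)          # only het daeSNP defined
      hap_a <- which(h[, 2] == 0)              # haplotype carrying A allele
      hap_b <- which(h[, 2] == 1)
      daesnpEffect * (h[hap_a, 1] - h[hap_b, 1])
    }
    ae_true <- vapply(hap_list, aeTrueAt, numeric(1))
    homBase <- function(g) ifelse(g == "AA", 2.5, ifelse(g == "BB", -2.5, 0))
    dna <- matrix(0, nVariants, nSamples, dimnames = dimnames(gt))
    rna <- dna
    for (i in seq_len(nVariants)) {
      base <- homBase(gt[i, ])
      dna[i, ] <- base + stats::rnorm(nSamples, 0, noiseSd)
      shift <- if (ids[i] == "daeSNP_1") ae_true else 0
      rna[i, ] <- base + shift + stats::rnorm(nSamples, 0, noiseSd)
    }
    intensity <- stats::runif(nVariants, 8.8, 12.5)
    intensity[1:2] <- stats::runif(2, 10, 12.5)    # planted pair stays analyzable
    ae <- AEMatrix(rna, dna, gt, variants, intensity)
    list(ae = ae,
         truth = list(daesnp_id = "daeSNP_1", rsnp_id = "rSNP_1",
                      effect = daesnpEffect, ld_r2 = ldR2,
                      rsnp_genotype = gt["rSNP_1", ]))
  })
}
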