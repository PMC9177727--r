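---
title: "Methods: Bayesian allelic expression imbalance and its decomposition"
author: "cisAEI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian allelic expression imbalance and its decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisAEI)
```

# The problem

A heterozygous somatic point mutation in a tumor need not be expressed at
the same level as the remaining wild-type allele. Two mechanisms push the
allelic balance of the transcript pool: the mutant allele may be present in
a different genomic copy number than the wild-type allele, and
cis-regulatory variation (inherited regulatory polymorphisms, somatic
noncoding mutations, allelic epigenetic states) may up- or down-regulate
one allele specifically. For an activating oncogenic mutation the
distinction matters clinically: a mutation on the highly expressed allele
should have greater functional impact than the same mutation on a silenced
allele.

`cisAEI` quantifies both mechanisms from paired DNA-seq and RNA-seq allelic
read counts at the mutated site, and separately measures normal-tissue
cis-regulation from microarray allelic intensities at common variants.

# The three log ratios

For a mutated locus with wild-type read count $X$ and mutant read count $Y$:

$$\beta = \log_2(Y_{\mathrm{DNA}}/X_{\mathrm{DNA}}), \qquad
  \alpha = \log_2(Y_{\mathrm{RNA}}/X_{\mathrm{RNA}}), \qquad
  \gamma = \alpha - \beta.$$

$\beta$ measures the allelic copy-number balance, $\alpha$ the net allelic
expression imbalance, and $\gamma$ the expression imbalance left after
normalizing for copy number — the cis-regulatory component. Positive values
favor the mutant allele.

## Posterior inference

Raw log ratios from shallow counts are unreliable, so each ratio gets a
posterior. With a Beta prior on the mutant-allele fraction $p$ and a
binomial read-count likelihood, the posterior is conjugate:

$$p \mid (Y, X) \sim \mathrm{Beta}(Y + a,\; X + b).$$

The log ratio is the monotone transform $\log_2 \frac{p}{1-p}$ of $p$, so
the maximum a posteriori (MAP) estimate is the transform of the posterior
mode and the credible interval is the transform of the equal-tailed
posterior quantiles. Calls use the interval-versus-zero rule: a sample is
imbalanced when its 89% CI does not cross zero, with the sign of the
interval deciding mutant- versus wild-type-preference.

Choices that were genuinely open, and how they were fixed:

* **Prior.** Default $\mathrm{Beta}(1, 1)$ (uniform), under which the MAP
  equals the raw $\log_2(Y/X)$, keeping the point estimate identical to the
  descriptive ratio. The Jeffreys prior $\mathrm{Beta}(0.5, 0.5)$ is
  supported through `posteriorSpec()`.
* **Interval type.** Equal-tailed (central) credible intervals rather than
  highest-posterior-density: they are invariant under the monotone log-odds
  transform, which HPD intervals are not, and they are reproducible without
  density estimation. The level is fixed at 0.89 by default.
* **Boundary counts.** A zero count puts the posterior mode on the boundary;
  the MAP is reported as an infinite sentinel while the CI remains finite
  for any positive prior, and classification uses only the CI. Samples with
  infinite MAPs are excluded (and counted) in the moment-based cohort
  analyses, where a variance is otherwise undefined.
* **The $\gamma$ posterior.** The MAP of $\gamma$ is computed as
  $\mathrm{MAP}(\alpha) - \mathrm{MAP}(\beta)$ — exact and deterministic.
  In general the mode of a difference is not the difference of modes, but at
  the read depths admitted by the $\geq 30$-read filter the discrepancy is
  below reporting precision, and the choice removes Monte-Carlo noise from
  the point estimate. Only the $\gamma$ CI is Monte-Carlo: independent
  draws from the two Beta posteriors propagated through the log2-odds
  difference, $2 \times 10^4$ draws by default (the equal-tailed interval of
  the draws is stable to well under 0.02 log2 units at these depths — the
  test suite checks this by doubling the draw count). Draws are made under
  a caller-supplied seed and the global RNG stream is restored afterwards;
  `profileCohort()` derives one seed per (sample, locus) pair from the base
  seed and the pair's rank in a sorted key order, making results independent
  of processing order.
* **Overdispersion.** The posterior is a pure Beta (binomial likelihood).
  Read-count overdispersion exists in the simulator (below) but is
  deliberately not modeled in the inference, whose contract is the
  conjugate Beta posterior; the calibration consequences are examined in
  the simulator section.

## Sample filters

Tumors enter the analysis when the mutation is missense and the summed
depth of both alleles is at least 30 reads in DNA-seq and at least 30 in
RNA-seq. The threshold is applied to the per-assay total (both alleles
together), not per allele. A sample carrying several missense mutations
contributes one profile per mutation by default; `collapse = "max-depth"`
keeps the deepest locus only, for analyses that need one row per patient.
Every exclusion carries a machine-readable reason code.

# Decomposing net allelic expression

Because $\gamma = \alpha - \beta$ by construction, the cohort variance
obeys the exact identity

$$\mathrm{Var}(\alpha) = \mathrm{Var}(\beta) + \mathrm{Var}(\gamma)
  + 2\,\mathrm{Cov}(\beta, \gamma),$$

and the cis-regulatory contribution to the variance of net allelic
expression is $(\mathrm{Var}(\gamma) + \mathrm{Cov}(\beta,
\gamma))/\mathrm{Var}(\alpha)$, with the copy-number contribution as its
exact complement. Moments use $n - 1$ denominators and are computed on MAP
point estimates (not posterior means or draws), matching how the per-sample
estimates are reported. Pearson correlations of $\alpha$ with $\beta$ and
with $\gamma$, and the $\beta/\gamma$ sign-quadrant tally (with exact zeros
in a separate tie bucket), complete the cohort description.

Among the gamma-imbalanced tumors, predominance of mutant-preference is
tested with the exact binomial test against 0.5 (two-sided by the
minimum-likelihood rule) with a Clopper–Pearson interval at the 0.89 level.
These are classical frequentist procedures chosen because they reproduce
the reported reference tallies exactly; a Bayesian interval for this
proportion is deliberately not offered.

# Normal-tissue differential allelic expression (DAE)

For microarray allelic intensities, the per-variant, per-sample allelic log
ratio is $\log_2(A) - \log_2(B)$ with alleles ordered alphabetically, and
the AE ratio is the RNA log ratio minus the DNA log ratio, defined only at
heterozygotes. Variants enter the analysis with mean RNA log2 allelic
intensity strictly greater than 9.5 and at least five heterozygous
samples; a two-sample Student's t test (het vs pooled hom RNA log ratios,
$P < 0.05$) screens for allelic signal. A heterozygote displays DAE when
$|\mathrm{AE}| \geq 0.58$ — inclusive, $0.58 = \log_2(1.5)$ rounded to two
decimals, i.e. at least a 1.5-fold difference between alleles. A variant is
a **daeSNP** when at least 10% of its heterozygotes, and no fewer than
three, display DAE.

Mapping looks for the regulatory variant behind a daeSNP: each candidate
within an inclusive ±250 kb window stratifies the daeSNP's absolute AE
ratios by candidate genotype, and a one-sided Mann–Whitney test asks
whether candidate heterozygotes show larger $|\mathrm{AE}|$ than the pooled
candidate homozygotes — the signature of an rSNP in incomplete linkage
disequilibrium with the daeSNP. P values are Benjamini–Hochberg adjusted
per daeSNP across its candidate window (configurable), significant at
$q \leq 0.05$. The rank test delegates to `stats::wilcox.test`, which uses
the exact null distribution for small tie-free groups and the
tie-corrected normal approximation otherwise. The eQTL check on total
expression uses Kruskal–Wallis for three genotype groups and Wilcoxon for
two.

# Clinical association and survival

Tumors are categorized purely by the $\gamma$ call: `gamma_mut`,
`gamma_wt`, `gamma_balanced`. Ratio-by-covariate comparisons use the
Wilcoxon rank-sum test with continuity correction (two levels) or
Kruskal–Wallis (more), BH-adjusted **per study** — cohorts are adjusted
separately, never pooled into one correction. Survival uses the standard
machinery from the `survival` package: Kaplan–Meier product-limit curves
compared by log-rank, with death from any cause as the overall-survival
endpoint, a separate disease-specific event flag, and censoring at last
contact. The multivariate Cox model reports hazard ratios with Wald 95%
intervals, codes the $\gamma$ category as a factor with `gamma_balanced`
as reference, and codes grade/stage as factors (their ordinality is not
imposed). Non-convergence and likely separation (SE of a log-HR above 100)
are flagged in the output, never silently dropped.

# The simulators

## Tumor cohorts

`simulateCohort()` generates the structure the tumor analysis assumes, so
every stage is testable without access-controlled patient data. Per tumor:
a true copy-number skew $\beta_0$ (present with probability
`pCnImbalance`, normal with spread `cnLogoddsSd` log2 units), a true cis
effect $\gamma_0$ (probability `pCisEffect`, normal at `cisLogoddsMean`
$\pm$ `cisLogoddsSd` — a positive mean encodes the mutant-preferring
skew), and a cellularity drawn from `cellularityRange` that attenuates the
cis effect in the bulk RNA signal ($\gamma_\mathrm{eff} = \gamma_0 \cdot
\mathrm{cellularity}$; DNA copy-number skew is treated as clonal and is not
attenuated — a simplification). Depths are negative-binomial (dispersion
size 20) around the configured means; counts are Beta-Binomial with
overdispersion `rho`. Receptor-status labels become more likely negative
(ER, PR) or positive (HER2) as $\gamma_\mathrm{eff}$ grows, and survival
is exponential with the hazard multiplied by `hrGammaMut` for tumors with
a true mutant-preferring cis effect, censored uniformly.

Defaults encode a plausible breast-tumor cohort: 94 tumors, mean depth 100
per assay, 70% with copy-number skew (spread 0.8 log2), 30% with a cis
effect centered at +0.8 log2 (so roughly a quarter to a third of tumors
are gamma-imbalanced and mutant-preference dominates), `rho = 0.01`,
cellularity 0.6–1, hazard ratio 2.1 (the ratio of a ~12.5-year to a
~5.9-year median survival under exponential hazards), seed 20220608.

The default overdispersion deserves a caveat: a Beta-Binomial with
$\rho = 0.01$ inflates count variance by a factor of roughly
$1 + (d - 1)\rho$ at depth $d$ — about 2 at depth 100, about 3 at depth
300 — while the pure-Beta posterior assumes none of it. Imbalance calls on
overdispersed data are therefore anti-conservative relative to the nominal
89% level, and the cross-depth error of the recovered $\gamma$ approaches a
noise floor set by $\rho$ rather than zero. This is intentional: it lets
the tests measure what extra-binomial noise does to the pipeline. The
checks whose purpose is the calibration of the interval machinery itself
(the balanced-cohort call rate, and the survival-separation preset, where
classification noise would otherwise confound the hazard signal) set
`rho = 0` so that the generator matches the inference model.

## Microarray panels

`simulateMicroarray()` plants one daeSNP, one regulatory variant (rSNP) in
incomplete LD with it ($r = \sqrt{\texttt{ldR2}}$, via explicit two-locus
haplotype frequencies), and null candidates across a ±200 kb span in a
64-sample panel — the default panel size of the normal-tissue setting this
emulates. Haplotypes carrying the rSNP up-allele express more, so daeSNP
heterozygotes who are also rSNP heterozygotes show an AE shift whose sign
follows phase: strong LD produces the unilateral AE distributions
characteristic of a nearby rSNP, weak LD bilateral ones. Homozygous array
log ratios sit near ±2.5 as on real genotyping arrays. What is *not*
simulated: realistic multi-locus LD blocks, genotyping error, imputation
uncertainty, intensity-dependent noise — so passing recovery tests show
the calling and mapping logic is correct, not that the method is robust to
array artifacts.

# Problem sizes and numerical checks

The verification suite uses sizes chosen to balance statistical resolution
against a small compute footprint, and states them here as the package's
own choices: credible bounds are compared with brute-force density
integration (numerical CDF inversion, tolerance $10^{-6}$) on 20 count
pairs; the variance identity is checked to $10^{-12}$ on 100 random
cohorts; calibration uses 2,000 balanced tumors at depth 100 (call rate at
most $0.11 + 3$ Monte-Carlo SEs); $\gamma$ recovery uses 400 tumors at
depths 30/100/300 (absolute bias below 0.05 log2 at depth 300, RMSE
decreasing in depth); cohort-direction and survival presets use 200–250
tumors, the latter over 30 seeds with the log-rank test required to reach
$P < 0.05$ in at least 80% of them. The acceptance script
(`scripts/acceptance.R`) recomputes all of these from scratch under a
caller-supplied seed.

# Known limitations

* One biallelic mutation model per locus; no haplotype phasing, no joint
  model across loci, and no purity/ploidy deconvolution — cellularity
  exists only in the simulator.
* The inference assumes binomial sampling; overdispersed data widen the
  true sampling distribution but not the posterior (see above).
* The DAE mapping tests one candidate at a time; candidates in LD with
  each other produce correlated, individually reported signals.
* Clinical simulators draw covariates independently except for their link
  to $\gamma$; real cohort confounding (age–grade–subtype structure) is
  not emulated, so clinical-module tests validate mechanics and power
  under clean conditions, not robustness to confounding.
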