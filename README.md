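# cisAEI

Bayesian analysis of **allelic expression imbalance (AEI)** at heterozygous
somatic point mutations, for tumor cohorts with paired DNA-seq and RNA-seq
allelic read counts — plus the companion normal-tissue **differential
allelic expression (DAE)** analysis of microarray allelic intensities.

It is written for cancer-genomics analysts who have per-sample allele
depths at a mutated site (e.g. a *PIK3CA* hotspot) and want to know not
just *whether* the mutant allele is over-expressed, but *why*: copy
number, or cis-regulation.

## The model

For each tumor, with wild-type read count *X* and mutant read count *Y*:

- β = log₂(Y_DNA / X_DNA) — the mutant allele's relative copy number;
- α = log₂(Y_RNA / X_RNA) — the net mutant allelic expression imbalance;
- γ = α − β — the imbalance attributable to cis-regulation alone.

Each ratio gets a conjugate Beta posterior over the mutant-allele fraction
(binomial likelihood), reported as a MAP estimate with an 89% equal-tailed
credible interval mapped through log₂ p/(1−p). A tumor is *imbalanced*
when the CI does not cross zero; the interval's sign gives
mutant-preferring vs wild-type-preferring. Cohort-level machinery includes
the exact variance decomposition

Var(α) = Var(β) + Var(γ) + 2 Cov(β, γ),

with the cis contribution (Var(γ) + Cov(β, γ)) / Var(α); an exact binomial
test for predominance of mutant-preference among γ-imbalanced tumors
(Clopper–Pearson 89% CI); DAE/daeSNP calling at |AE| ≥ 0.58 (1.5-fold)
with ±250 kb Mann–Whitney mapping of candidate regulatory variants; and
clinical association (Wilcoxon/Kruskal–Wallis with per-study BH
adjustment) and survival analysis (Kaplan–Meier/log-rank, multivariate
Cox) of tumors categorized by their γ call. Seeded simulators generate
tumor cohorts and microarray panels with known truth so the whole pipeline
is testable without access-controlled data. See the methods vignette
(`vignettes/allelic-imbalance-methods.Rmd`) for assumptions and design
choices.

## Worked example

```r
library(cisAEI)

## one tumor: mutant allele at normal copy number but over-expressed
profileSample(dnaMut = 48, dnaWt = 50, rnaMut = 70, rnaWt = 30)
#>   alpha_map alpha_lo alpha_hi alpha_call beta_map beta_lo beta_hi beta_call
#> 1      1.22    0.716     1.72     mutant  -0.0589  -0.522   0.405  balanced
#>   gamma_map gamma_lo gamma_hi gamma_call
#> 1      1.28    0.582     1.96     mutant

## a simulated 94-tumor cohort, end to end
sim      <- simulateCohort(simulationConfig(nSamples = 94, seed = 1))
profiles <- profileCohort(filterSamples(sim$counts), posteriorSpec(seed = 1))
profiles
#> SampleProfiles: 94 profiles (94 samples)
#> gamma calls: 58 balanced, 27 mutant, 9 wildtype
#> ...

dec <- varianceDecomposition(profiles$beta_map, profiles$gamma_map)
sprintf("cis contribution: %.1f%%", 100 * dec$cis_contribution)
#> "cis contribution: 36.7%"

prev <- gammaPrevalence(profiles)
#> mutant preference: 27/36 (Prob. = 0.75), 89% CI [0.61, 0.86], P = 0.0039
```

The single-tumor call reads: net expression strongly favors the mutant
allele (α CI entirely above zero) with balanced DNA (β CI crosses zero),
so the imbalance is cis-regulatory (γ mutant-preferring). In the cohort,
36 of 94 tumors are γ-imbalanced, 27 of those prefer the mutant allele
(exact binomial P = 0.0039 against 0.5), and cis-regulation explains about
37% of the variance in net allelic expression under this simulation
preset.

`runPipeline()` chains the stages (simulate or read TSV/VCF → filter →
infer → decompose → prevalence → categorize → survival) and writes
per-stage outputs with a `manifest.json`.

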