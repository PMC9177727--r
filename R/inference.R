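#' Beta posterior over the mutant-allele fraction
#'
#' Conjugate update of the Beta prior in `spec` with the observed
#' mutant (Y) and wild-type (X) read counts: the posterior over the
#' mutant-allele fraction p is `Beta(Y + priorA, X + priorB)`.
#'
#' @param mutReads,wtReads non-negative read counts (not both zero).
#' @param spec a [PosteriorSpec-class] (defaults to the uniform prior).
#' @return named numeric vector `c(shape1=, shape2=)` of the posterior
#'   Beta parameters.
#' @examples
#' allelePosterior(50, 50)        # Beta(51, 51), mode 0.5
#' allelePosterior(75, 25)        # mode 0.75
#' @export
allelePosterior <- function(mutReads, wtReads, spec = posteriorSpec()) {
  stopIfNot(length(mutReads) == 1 && length(wtReads) == 1,
            "scalar counts expected")
  stopIfNot(mutReads >= 0 && wtReads >= 0, "read counts must be non-negative")
  stopIfNot(mutReads + wtReads > 0,
            "both read counts are zero: no information about the allelic fraction")
  c(shape1 = unname(mutReads) + spec@priorA,
    shape2 = unname(wtReads) + spec@priorB)
}

# Mode of Beta(a, b) on [0, 1]; boundary modes at 0/1, flat prior -> 0.5.
.betaMode <- function(a, b) {
  if (a > 1 && b > 1) (a - 1) / (a + b - 2)
  else if (a <= 1 && b > 1) 0
  else if (a > 1 && b <= 1) 1
  else 0.5   # a == b == 1 exactly (flat); a,b < 1 bimodal excluded by counts > 0
}

.ciCall <- function(lo, hi) {
  if (lo <= 0 && hi >= 0) "balanced" else if (lo > 0) "mutant" else "wildtype"
}

#' MAP and credible interval of an allelic log2 ratio
#'
#' Maps a Beta posterior over the mutant-allele fraction p to the
#' log2 mutant/wild-type ratio scale via the monotone transform
#' `log2(p / (1 - p))`. The MAP is the transform of the posterior
#' mode (reported as -Inf/Inf when the mode sits on the boundary);
#' the credible interval is the equal-tailed interval of p at the
#' given level mapped through the same transform, hence finite for
#' any positive prior. A sample is called imbalanced when the CI
#' does not cross zero: "mutant" when the whole interval is positive,
#' "wildtype" when negative, "balanced" otherwise.
#'
#' @param posterior Beta parameters as returned by [allelePosterior()].
#' @param level credible level (default 0.89).
#' @return a list with elements `map`, `lo`, `hi` (log2 units) and
#'   `call`.
#' @examples
#' logRatioEstimate(allelePosterior(75, 25))   # map = log2(3)
#' @export
logRatioEstimate <- function(posterior, level = 0.89) {
  a <- posterior[["shape1"]]; b <- posterior[["shape2"]]
  stopIfNot(level > 0 && level < 1, "level must be in (0, 1)")
  p_hat <- .betaMode(a, b)
  q <- stats::qbeta(c((1 - level) / 2, (1 + level) / 2), a, b)
  lo <- log2Odds(q[1]); hi <- log2Odds(q[2])
  list(map = log2Odds(p_hat), lo = lo, hi = hi, call = .ciCall(lo, hi))
}

#' Gamma (cis-regulatory) log-ratio estimate
#'
#' The gamma ratio is the RNA log2 allelic ratio (alpha) minus the DNA
#' log2 allelic ratio (beta): the allelic expression imbalance left
#' after normalizing for allelic copy number. Its MAP is computed as
#' MAP(alpha) - MAP(beta), which is exact and deterministic; the
#' credible interval comes from seeded Monte-Carlo draws of the two
#' independent Beta posteriors propagated through the log2-odds
#' difference (equal-tailed interval of the draws).
#'
#' @param alphaPosterior Beta posterior of the RNA mutant-allele
#'   fraction ([allelePosterior()] on the RNA counts).
#' @param betaPosterior Beta posterior of the DNA mutant-allele
#'   fraction.
#' @param spec a [PosteriorSpec-class]; `spec@nDraws` draws are made
#'   under `spec@seed` (the caller's RNG state is untouched).
#' @param level credible level (default 0.89).
#' @return a list with elements `map`, `lo`, `hi` (log2 units) and
#'   `call`.
#' @examples
#' a <- allelePosterior(80, 20); b <- allelePosterior(50, 50)
#' gammaEstimate(a, b)        # map = log2(4) = 2
#' @export
gammaEstimate <- function(alphaPosterior, betaPosterior,
                          spec = posteriorSpec(), level = 0.89) {
  stopIfNot(spec@nDraws >= 1e4, "nDraws below the 1e4 floor")
  map_a <- log2Odds(.betaMode(alphaPosterior[["shape1"]],
                              alphaPosterior[["shape2"]]))
  map_b <- log2Odds(.betaMode(betaPosterior[["shape1"]],
                              betaPosterior[["shape2"]]))
  map_g <- map_a - map_b            # Inf - Inf -> NaN sentinel, CI still ok
  draws <- withSeed(spec@seed, {
    p_rna <- stats::rbeta(spec@nDraws, alphaPosterior[["shape1"]],
                          alphaPosterior[["shape2"]])
    p_dna <- stats::rbeta(spec@nDraws, betaPosterior[["shape1"]],
                          betaPosterior[["shape2"]])
    log2Odds(p_rna) - log2Odds(p_dna)
  })
  qs <- stats::quantile(draws, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE)
  list(map = map_g, lo = qs[1], hi = qs[2], call = .ciCall(qs[1], qs[2]))
}

#' Profile one tumor mutation: alpha, beta and gamma estimates
#'
#' Computes the three allelic log ratios for one (sample, locus) pair
#' from its DNA and RNA allelic read counts:
#' beta = log2(Y_DNA / X_DNA) (allelic copy number),
#' alpha = log2(Y_RNA / X_RNA) (net allelic expression), and
#' gamma = alpha - beta (cis-regulatory component), each with MAP,
#' 89% credible interval and imbalance call.
#'
#' @param dnaMut,dnaWt DNA-seq mutant/wild-type read counts.
#' @param rnaMut,rnaWt RNA-seq mutant/wild-type read counts.
#' @param spec a [PosteriorSpec-class].
#' @param level credible level (default 0.89).
#' @return a one-row `data.frame` with columns
#'   `alpha_map alpha_lo alpha_hi alpha_call beta_* gamma_*`.
#' @export
profileSample <- function(dnaMut, dnaWt, rnaMut, rnaWt,
                          spec = posteriorSpec(), level = 0.89) {
  post_b <- allelePosterior(dnaMut, dnaWt, spec)
  post_a <- allelePosterior(rnaMut, rnaWt, spec)
  est_a <- logRatioEstimate(post_a, level)
  est_b <- logRatioEstimate(post_b, level)
  est_g <- gammaEstimate(post_a, post_b, spec, level)
  data.frame(
    alpha_map = est_a$map, alpha_lo = est_a$lo, alpha_hi = est_a$hi,
    alpha_call = est_a$call,
    beta_map = est_b$map, beta_lo = est_b$lo, beta_hi = est_b$hi,
    beta_call = est_b$call,
    gamma_map = est_g$map, gamma_lo = est_g$lo, gamma_hi = est_g$hi,
    gamma_call = est_g$call,
    stringsAsFactors = FALSE)
}

#' Profile a cohort of filtered allelic counts
#'
#' Runs [profileSample()] on every (sample, locus) pair that has both
#' a DNA and an RNA record, typically the output of [filterSamples()].
#' Each pair gets its own deterministic gamma Monte-Carlo seed derived
#' from `spec@seed` and the pair's rank, so results are reproducible
#' and independent of processing order.
#'
#' @param counts an [AllelicCounts-class] object.
#' @param spec a [PosteriorSpec-class].
#' @param level credible level (default 0.89).
#' @return a [SampleProfiles-class] object, one row per (sample,
#'   locus), carrying the read depths alongside the estimates.
#' @export
profileCohort <- function(counts, spec = posteriorSpec(), level = 0.89) {
  stopIfNot(is(counts, "AllelicCounts"), "counts must be an AllelicCounts")
  df <- as.data.frame(counts)
  df$key <- paste(df$sample_id, df$chrom, df$pos, sep = "\r")
  keys <- sort(unique(df$key))
  rows <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    sub <- df[df$key == keys[i], ]
    dna <- sub[sub$assay == "DNA", ]
    rna <- sub[sub$assay == "RNA", ]
    if (nrow(dna) != 1 || nrow(rna) != 1) next
    pair_spec <- posteriorSpec(spec@priorA, spec@priorB, spec@nDraws,
                               seed = (spec@seed + i) %% .Machine$integer.max)
    est <- profileSample(dna$mut_reads, dna$wt_reads,
                         rna$mut_reads, rna$wt_reads, pair_spec, level)
    rows[[i]] <- cbind(
      data.frame(sample_id = dna$sample_id, chrom = dna$chrom, pos = dna$pos,
                 dna_depth = dna$wt_reads + dna$mut_reads,
                 rna_depth = rna$wt_reads + rna$mut_reads,
                 stringsAsFactors = FALSE),
      est)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  stopIfNot(length(rows) > 0, "no (sample, locus) pair has both assays")
  out <- new("SampleProfiles", DataFrame(do.call(rbind, rows)))
  metadata(out)$level <- level
  metadata(out)$prior <- c(spec@priorA, spec@priorB)
  out
}

#' Write sample profiles to TSV or JSON
#'
#' @param profiles a [SampleProfiles-class] object.
#' @param path output path; format chosen by extension (`.json` for
#'   JSON, otherwise TSV).
#' @return `path`, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  df <- as.data.frame(profiles)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
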