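#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

.ASSAY_LEVELS <- c("DNA", "RNA")
.MUTATION_CLASSES <- c("missense", "other")
.GENOTYPE_LEVELS <- c("AA", "AB", "BB")

.COUNT_COLUMNS <- c("sample_id", "chrom", "pos", "assay",
                    "wt_reads", "mut_reads", "mutation_class")

#' AllelicCounts: per-sample, per-locus allelic read counts
#'
#' A `DataFrame` subclass holding one record per (sample, locus, assay)
#' with wild-type (X) and mutant (Y) read counts at a heterozygous
#' somatic point mutation. Records come in pairs: a DNA-seq record
#' measuring the allelic copy-number balance and an RNA-seq record
#' measuring allelic expression.
#'
#' Required columns: `sample_id`, `chrom`, `pos` (1-based), `assay`
#' ("DNA" or "RNA"), `wt_reads`, `mut_reads` (non-negative integers),
#' `mutation_class` ("missense" or "other").
#'
#' @seealso [readAllelicCounts()], [filterSamples()], [profileCohort()]
#' @export
setClass("AllelicCounts", contains = "DFrame")

.validAllelicCounts <- function(object) {
  msg <- NULL
  missing_cols <- setdiff(.COUNT_COLUMNS, colnames(object))
  if (length(missing_cols))
    msg <- c(msg, paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (is.null(msg)) {
    if (!all(object$assay %in% .ASSAY_LEVELS))
      msg <- c(msg, "assay must be 'DNA' or 'RNA'")
    if (!all(object$mutation_class %in% .MUTATION_CLASSES))
      msg <- c(msg, "mutation_class must be 'missense' or 'other'")
    bad <- !is.na(object$wt_reads) & !is.na(object$mut_reads) &
      (object$wt_reads < 0 | object$mut_reads < 0)
    if (any(bad))
      msg <- c(msg, paste("negative read counts in rows:",
                          paste(utils::head(which(bad), 5), collapse = ", ")))
    key <- paste(object$sample_id, object$chrom, object$pos, object$assay)
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (sample, locus, assay) records")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("AllelicCounts", .validAllelicCounts)

#' Construct an AllelicCounts object
#'
#' @param data a `data.frame` or `DataFrame` with the required columns
#'   (see [AllelicCounts-class]).
#' @return an `AllelicCounts` object.
#' @examples
#' AllelicCounts(data.frame(
#'   sample_id = "S1", chrom = "chr3", pos = 178936091L,
#'   assay = c("DNA", "RNA"), wt_reads = c(50L, 30L),
#'   mut_reads = c(48L, 70L), mutation_class = "missense"))
#' @export
AllelicCounts <- function(data) {
  df <- S4Vectors::DataFrame(data)
  df$assay <- as.character(df$assay)
  df$mutation_class <- as.character(df$mutation_class)
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$wt_reads <- as.integer(df$wt_reads)
  df$mut_reads <- as.integer(df$mut_reads)
  new("AllelicCounts", df)
}

setMethod("show", "AllelicCounts", function(object) {
  cat(sprintf("AllelicCounts: %d records, %d samples, %d loci\n",
              nrow(object), length(unique(object$sample_id)),
              length(unique(paste(object$chrom, object$pos)))))
  callNextMethod()
})

#' Sample identifiers of an AllelicCounts or SampleProfiles object
#'
#' @param x an `AllelicCounts` or `SampleProfiles` object.
#' @return character vector of unique sample identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "AllelicCounts", function(x) unique(x$sample_id))

.PROFILE_COLUMNS <- c("sample_id", "chrom", "pos",
                      "alpha_map", "alpha_lo", "alpha_hi", "alpha_call",
                      "beta_map", "beta_lo", "beta_hi", "beta_call",
                      "gamma_map", "gamma_lo", "gamma_hi", "gamma_call")

#' SampleProfiles: per-tumor allelic imbalance estimates
#'
#' A `DataFrame` subclass with one row per retained (sample, locus)
#' holding the MAP estimate, credible-interval bounds (log2 units) and
#' imbalance call for each of the three allelic log ratios:
#' alpha (RNA, net allelic expression), beta (DNA, allelic copy number)
#' and gamma = alpha - beta (cis-regulatory component).
#' Calls are "balanced", "mutant" (CI entirely above zero) or
#' "wildtype" (CI entirely below zero).
#'
#' @seealso [profileCohort()], [categorizeGamma()]
#' @export
setClass("SampleProfiles", contains = "DFrame")

setValidity("SampleProfiles", function(object) {
  missing_cols <- setdiff(.PROFILE_COLUMNS, colnames(object))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  calls <- c(object$alpha_call, object$beta_call, object$gamma_call)
  if (!all(calls %in% c("balanced", "mutant", "wildtype")))
    return("calls must be 'balanced', 'mutant' or 'wildtype'")
  TRUE
})

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SampleProfiles", function(x) unique(x$sample_id))

setMethod("show", "SampleProfiles", function(object) {
  cat(sprintf("SampleProfiles: %d profiles (%d samples)\n",
              nrow(object), length(unique(object$sample_id))))
  if (nrow(object)) {
    tab <- table(factor(object$gamma_call,
                        levels = c("balanced", "mutant", "wildtype")))
    cat(sprintf("gamma calls: %d balanced, %d mutant, %d wildtype\n",
                tab[["balanced"]], tab[["mutant"]], tab[["wildtype"]]))
  }
  callNextMethod()
})

#' PosteriorSpec: prior and Monte-Carlo settings for imbalance inference
#'
#' Bundles the Beta prior pseudo-counts placed on the mutant-allele
#' fraction, the number of Monte-Carlo draws used for the gamma
#' credible interval, and the seed making those draws reproducible.
#'
#' @slot priorA,priorB positive Beta prior shape parameters
#'   (pseudo-counts for the mutant and wild-type allele). Default
#'   `Beta(1, 1)` (uniform); `Beta(0.5, 0.5)` gives the Jeffreys prior.
#' @slot nDraws number of Monte-Carlo draws for the gamma posterior
#'   (at least 1e4).
#' @slot seed integer seed for the gamma draws.
#' @seealso [posteriorSpec()], [gammaEstimate()]
#' @export
setClass("PosteriorSpec",
         representation(priorA = "numeric", priorB = "numeric",
                        nDraws = "integer", seed = "integer"))

setValidity("PosteriorSpec", function(object) {
  msg <- NULL
  if (object@priorA <= 0 || object@priorB <= 0)
    msg <- c(msg, "prior pseudo-counts must be positive")
  if (object@nDraws < 1e4)
    msg <- c(msg, "nDraws must be at least 1e4")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PosteriorSpec
#'
#' @param priorA,priorB Beta prior shape parameters (default uniform
#'   `Beta(1, 1)`).
#' @param nDraws Monte-Carlo draws for the gamma credible interval.
#' @param seed integer seed used for the gamma draws.
#' @return a `PosteriorSpec` object.
#' @examples
#' posteriorSpec()                      # uniform prior
#' posteriorSpec(0.5, 0.5)              # Jeffreys prior
#' @export
posteriorSpec <- function(priorA = 1, priorB = 1, nDraws = 2e4L,
                          seed = 20220608L) {
  new("PosteriorSpec", priorA = priorA, priorB = priorB,
      nDraws = as.integer(nDraws), seed = as.integer(seed))
}

setMethod("show", "PosteriorSpec", function(object) {
  cat(sprintf("PosteriorSpec: Beta(%g, %g) prior, %d gamma draws, seed %d\n",
              object@priorA, object@priorB, object@nDraws, object@seed))
})

#' AEMatrix: microarray allelic log-ratios with genotypes
#'
#' A `RangedSummarizedExperiment` subclass for normal-tissue
#' differential allelic expression (DAE) analysis. Rows are variants
#' (with genomic positions and the alphabetically ordered alleles A/B),
#' columns are samples. Assays:
#' \describe{
#'   \item{rnaLogRatio}{log2(A) - log2(B) of RNA allelic intensities}
#'   \item{dnaLogRatio}{log2(A) - log2(B) of DNA allelic intensities}
#'   \item{genotype}{"AA", "AB", "BB" or NA}
#' }
#' `rowData` carries `allele_a`, `allele_b` and `rna_mean_intensity`
#' (mean RNA log2 allelic intensity, used for variant filtering).
#' The allelic-expression (AE) ratio, RNA log-ratio minus DNA
#' log-ratio, is defined only at heterozygous ("AB") samples.
#'
#' @seealso [AEMatrix()], [aeRatio()], [callDAE()], [daeMapping()]
#' @export
setClass("AEMatrix", contains = "RangedSummarizedExperiment")

setValidity("AEMatrix", function(object) {
  msg <- NULL
  needed <- c("rnaLogRatio", "dnaLogRatio", "genotype")
  missing_assays <- setdiff(needed, SummarizedExperiment::assayNames(object))
  if (length(missing_assays))
    msg <- c(msg, paste("missing assays:", paste(missing_assays, collapse = ", ")))
  needed_rd <- c("allele_a", "allele_b", "rna_mean_intensity")
  rd <- SummarizedExperiment::rowData(object)
  missing_rd <- setdiff(needed_rd, colnames(rd))
  if (length(missing_rd))
    msg <- c(msg, paste("missing rowData columns:", paste(missing_rd, collapse = ", ")))
  if (!length(msg)) {
    gt <- SummarizedExperiment::assay(object, "genotype")
    if (!all(gt %in% c(.GENOTYPE_LEVELS, NA)))
      msg <- c(msg, "genotype must be 'AA', 'AB', 'BB' or NA")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an AEMatrix
#'
#' @param rnaLogRatio,dnaLogRatio numeric variant-by-sample matrices of
#'   log2 allelic intensity ratios (allele A over allele B).
#' @param genotype character variant-by-sample matrix of genotype calls
#'   ("AA", "AB", "BB", or NA for missing).
#' @param variants a `data.frame` (or `GRanges`) with one row per
#'   variant: `variant_id`, `chrom`, `pos`, `allele_a`, `allele_b`.
#'   Alleles are ordered alphabetically: A is the lexicographically
#'   smaller allele.
#' @param rnaMeanIntensity numeric vector of per-variant mean RNA log2
#'   allelic intensities.
#' @return an `AEMatrix` object.
#' @export
AEMatrix <- function(rnaLogRatio, dnaLogRatio, genotype, variants,
                     rnaMeanIntensity) {
  if (is(variants, "GRanges")) {
    gr <- variants
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = variants$chrom,
      ranges = IRanges::IRanges(start = variants$pos, width = 1L))
    names(gr) <- variants$variant_id
    gr$allele_a <- variants$allele_a
    gr$allele_b <- variants$allele_b
  }
  gr$rna_mean_intensity <- rnaMeanIntensity
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rnaLogRatio = rnaLogRatio, dnaLogRatio = dnaLogRatio,
                  genotype = genotype),
    rowRanges = gr)
  new("AEMatrix", se)
}

setMethod("show", "AEMatrix", function(object) {
  cat(sprintf("AEMatrix: %d variants x %d samples\n",
              nrow(object), ncol(object)))
  callNextMethod()
})
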