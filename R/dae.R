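#' Allelic-expression ratios from an AEMatrix
#'
#' The AE ratio at a variant in a sample is the RNA log2 allelic
#' ratio minus the DNA log2 allelic ratio, normalizing expression for
#' allelic DNA content. It is defined only at heterozygous ("AB")
#' samples; all other entries are NA. Swapping the A/B allele labels
#' flips the sign of both log ratios and hence of the AE ratio.
#'
#' @param x an [AEMatrix-class] object.
#' @return numeric variant-by-sample matrix of AE ratios.
#' @export
setGeneric("aeRatio", function(x) standardGeneric("aeRatio"))

#' @rdname aeRatio
#' @export
setMethod("aeRatio", "AEMatrix", function(x) {
  ae <- SummarizedExperiment::assay(x, "rnaLogRatio") -
    SummarizedExperiment::assay(x, "dnaLogRatio")
  ae[SummarizedExperiment::assay(x, "genotype") != "AB"] <- NA_real_
  ae[is.na(SummarizedExperiment::assay(x, "genotype"))] <- NA_real_
  ae
})

#' Filter microarray variants for DAE analysis
#'
#' Keeps variants with mean RNA log2 allelic intensity strictly
#' greater than `minIntensity` and at least `minHet` heterozygous
#' samples.
#'
#' @param x an [AEMatrix-class] object.
#' @param minIntensity intensity cutoff (default 9.5, exclusive).
#' @param minHet minimum heterozygote count (default 5).
#' @return the filtered [AEMatrix-class]; excluded variants and
#'   reasons are recorded in `metadata(..)$excluded_variants`.
#' @export
filterVariants <- function(x, minIntensity = 9.5, minHet = 5) {
  stopIfNot(is(x, "AEMatrix"), "x must be an AEMatrix")
  gt <- SummarizedExperiment::assay(x, "genotype")
  n_het <- rowSums(gt == "AB", na.rm = TRUE)
  intensity <- SummarizedExperiment::rowData(x)$rna_mean_intensity
  keep <- intensity > minIntensity & n_het >= minHet
  reason <- ifelse(intensity <= minIntensity, "low_intensity", "few_heterozygotes")
  out <- x[keep, ]
  metadata(out)$excluded_variants <- data.frame(
    variant_id = rownames(x)[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Heterozygote vs homozygote test on RNA log ratios
#'
#' For each variant, a two-sample Student's t test comparing RNA log
#' ratios of heterozygous (AB) samples against the combined homozygous
#' (AA and BB) samples. Variants where a genuine allelic-expression
#' signal exists show het log ratios displaced (in either direction)
#' from the hom cluster. Variants with fewer than 2 samples in either
#' group are skipped with a reason.
#'
#' @param x an [AEMatrix-class] object.
#' @param alpha significance cutoff on the unadjusted P (default 0.05).
#' @return a `DataFrame` with one row per variant: `variant_id`,
#'   `n_het`, `n_hom`, `p_value`, `significant`, `skipped_reason`.
#' @export
hetVsHomTest <- function(x, alpha = 0.05) {
  stopIfNot(is(x, "AEMatrix"), "x must be an AEMatrix")
  gt <- SummarizedExperiment::assay(x, "genotype")
  rna <- SummarizedExperiment::assay(x, "rnaLogRatio")
  rows <- lapply(seq_len(nrow(x)), function(i) {
    het <- rna[i, !is.na(gt[i, ]) & gt[i, ] == "AB"]
    hom <- rna[i, !is.na(gt[i, ]) & gt[i, ] %in% c("AA", "BB")]
    het <- het[is.finite(het)]; hom <- hom[is.finite(hom)]
    if (length(het) < 2 || length(hom) < 2) {
      return(data.frame(variant_id = rownames(x)[i],
                        n_het = length(het), n_hom = length(hom),
                        p_value = NA_real_, significant = NA,
                        skipped_reason = "group_too_small",
                        stringsAsFactors = FALSE))
    }
    p <- stats::t.test(het, hom)$p.value
    data.frame(variant_id = rownames(x)[i], n_het = length(het),
               n_hom = length(hom), p_value = p, significant = p < alpha,
               skipped_reason = NA_character_, stringsAsFactors = FALSE)
  })
  DataFrame(do.call(rbind, rows))
}

#' Call differential allelic expression (DAE) and daeSNPs
#'
#' A heterozygous sample displays DAE at a variant when its absolute
#' AE ratio is at least `threshold` log2 units (default 0.58, i.e. a
#' 1.5-fold or greater difference between alleles; the comparison is
#' inclusive). A variant is a daeSNP when at least 10% of its
#' heterozygous samples, and no fewer than three, display DAE.
#'
#' @param x an [AEMatrix-class] object.
#' @param threshold absolute AE ratio cutoff in log2 units
#'   (default `round(log2(1.5), 2)` = 0.58).
#' @param minFrac,minCount daeSNP rule: minimum fraction (default
#'   0.10) and minimum count (default 3) of DAE-displaying
#'   heterozygotes.
#' @return a `DataFrame` with one row per variant: `variant_id`,
#'   `n_het`, `n_dae`, `frac_dae`, `is_daesnp`, `het_vs_hom_p`;
#'   per-sample flags are attached as a matrix in
#'   `metadata(..)$dae_flags`. Variants with no heterozygotes are
#'   reported with `n_het = 0` and `is_daesnp = NA`.
#' @export
callDAE <- function(x, threshold = 0.58, minFrac = 0.10, minCount = 3) {
  stopIfNot(is(x, "AEMatrix"), "x must be an AEMatrix")
  stopIfNot(threshold > 0, "threshold must be positive")
  ae <- aeRatio(x)
  flags <- abs(ae) >= threshold            # NA where AE undefined
  hvh <- hetVsHomTest(x)
  n_het <- unname(rowSums(!is.na(ae)))
  n_dae <- unname(rowSums(flags, na.rm = TRUE))
  frac <- ifelse(n_het > 0, n_dae / n_het, NA_real_)
  res <- DataFrame(
    variant_id = rownames(x),
    n_het = as.integer(n_het),
    n_dae = as.integer(n_dae),
    frac_dae = frac,
    is_daesnp = ifelse(n_het > 0, frac >= minFrac & n_dae >= minCount, NA),
    het_vs_hom_p = hvh$p_value)
  metadata(res)$dae_flags <- flags
  metadata(res)$threshold <- threshold
  res
}

#' Map candidate regulatory variants around a daeSNP
#'
#' Stratifies the AE ratios observed at a daeSNP by the genotype at
#' each candidate variant within a +/- `window` bp window (inclusive
#' at both ends). If the candidate is the regulatory variant (rSNP),
#' samples heterozygous at it should show larger absolute AE at the
#' daeSNP than samples homozygous at it, so a one-sided Mann-Whitney
#' (Wilcoxon rank-sum) test compares |AE| of candidate heterozygotes
#' against the combined candidate homozygotes (alternative: het
#' greater). P values are Benjamini-Hochberg adjusted across the
#' candidates of this daeSNP; candidates are significant at
#' `q <= bhAlpha`.
#'
#' @param x an [AEMatrix-class] object.
#' @param daeSnp variant id of the daeSNP whose AE ratios are mapped.
#' @param window half-width of the cis window in bp (default 250000,
#'   inclusive).
#' @param bhAlpha FDR cutoff (default 0.05).
#' @return a `DataFrame` with one row per candidate: `dae_snp_id`,
#'   `candidate_snp_id`, `distance` (bp, signed), `n_het`, `n_hom`,
#'   `p_value` (one-sided), `q_value`, `significant`,
#'   `skipped_reason`.
#' @export
daeMapping <- function(x, daeSnp, window = 250000, bhAlpha = 0.05) {
  stopIfNot(is(x, "AEMatrix"), "x must be an AEMatrix")
  stopIfNot(daeSnp %in% rownames(x), sprintf("unknown daeSNP '%s'", daeSnp))
  gr <- SummarizedExperiment::rowRanges(x)
  pos <- GenomicRanges::start(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  i0 <- match(daeSnp, rownames(x))
  dist <- pos - pos[i0]
  in_window <- chrom == chrom[i0] & abs(dist) <= window &
    rownames(x) != daeSnp
  cand <- which(in_window)
  if (!length(cand)) {
    return(DataFrame(dae_snp_id = character(0), candidate_snp_id = character(0),
                     distance = integer(0), n_het = integer(0),
                     n_hom = integer(0), p_value = numeric(0),
                     q_value = numeric(0), significant = logical(0),
                     skipped_reason = character(0)))
  }
  ae0 <- abs(aeRatio(x)[i0, ])
  gt <- SummarizedExperiment::assay(x, "genotype")
  rows <- lapply(cand, function(j) {
    g <- gt[j, ]
    usable <- !is.na(ae0) & !is.na(g)
    het <- ae0[usable & g == "AB"]
    hom <- ae0[usable & g %in% c("AA", "BB")]
    if (length(het) < 2 || length(hom) < 2) {
      return(data.frame(dae_snp_id = daeSnp,
                        candidate_snp_id = rownames(x)[j],
                        distance = dist[j], n_het = length(het),
                        n_hom = length(hom), p_value = NA_real_,
                        skipped_reason = "group_too_small",
                        stringsAsFactors = FALSE))
    }
    p <- suppressWarnings(
      stats::wilcox.test(het, hom, alternative = "greater")$p.value)
    data.frame(dae_snp_id = daeSnp, candidate_snp_id = rownames(x)[j],
               distance = dist[j], n_het = length(het), n_hom = length(hom),
               p_value = p, skipped_reason = NA_character_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  tested <- !is.na(res$p_value)
  res$q_value[tested] <- stats::p.adjust(res$p_value[tested], method = "BH")
  res$significant <- !is.na(res$q_value) & res$q_value <= bhAlpha
  DataFrame(res[, c("dae_snp_id", "candidate_snp_id", "distance", "n_het",
                    "n_hom", "p_value", "q_value", "significant",
                    "skipped_reason")])
}

#' Expression quantitative trait locus (eQTL) test
#'
#' Tests whether total expression differs by genotype at a candidate
#' variant: Kruskal-Wallis rank-sum test when three genotype groups
#' are usable, Wilcoxon rank-sum when two.
#'
#' @param expression numeric vector of per-sample expression values.
#' @param genotypes character vector of genotype calls ("AA", "AB",
#'   "BB"); groups with fewer than `minGroup` samples are dropped.
#' @param minGroup minimum samples per usable genotype group
#'   (default 2).
#' @return a list with `p_value`, `method`, and `group_sizes`.
#' @export
eqtlTest <- function(expression, genotypes, minGroup = 2) {
  stopIfNot(length(expression) == length(genotypes),
            "expression and genotypes must be paired")
  ok <- is.finite(expression) & !is.na(genotypes)
  e <- expression[ok]; g <- as.character(genotypes[ok])
  sizes <- table(g)
  usable <- names(sizes)[sizes >= minGroup]
  stopIfNot(length(usable) >= 2,
            "need at least 2 genotype groups with enough samples")
  sel <- g %in% usable
  e <- e[sel]; g <- factor(g[sel])
  if (nlevels(g) == 2) {
    sp <- split(e, g)
    p <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]])$p.value)
    method <- "wilcoxon"
  } else {
    p <- stats::kruskal.test(e, g)$p.value
    method <- "kruskal-wallis"
  }
  list(p_value = p, method = method, group_sizes = as.list(table(g)))
}
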