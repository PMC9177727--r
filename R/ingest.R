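#' Read allelic read counts from a TSV table or a VCF
#'
#' Reads per-sample, per-locus wild-type and mutant read counts.
#' Two formats are supported:
#' \describe{
#'   \item{tsv}{a tab-separated table with header
#'     `sample_id chrom pos assay wt_reads mut_reads mutation_class`.}
#'   \item{vcf}{a VCF 4.x file with a per-sample `AD` (allele depth)
#'     FORMAT field. Each biallelic record yields one `AllelicCounts`
#'     row per sample with non-missing AD; the REF depth maps to
#'     `wt_reads` and the first ALT depth to `mut_reads`. The assay is
#'     taken from the `ASSAY` INFO field if present, else `assay`
#'     must be supplied; `mutation_class` is "missense" when the
#'     `CLASS` INFO field says so, "other" otherwise (or the
#'     `mutationClass` argument when the field is absent).}
#' }
#' Malformed rows are rejected with row-addressed error messages.
#'
#' @param path path to the input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param assay for VCF input without an `ASSAY` INFO field: the assay
#'   label ("DNA" or "RNA") to attach to every record.
#' @param mutationClass for VCF input without a `CLASS` INFO field:
#'   the mutation class to attach ("missense" or "other").
#' @return an [AllelicCounts-class] object.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tchrom\tpos\tassay\twt_reads\tmut_reads\tmutation_class",
#'              "S1\tchr3\t178936091\tDNA\t50\t48\tmissense",
#'              "S1\tchr3\t178936091\tRNA\t30\t70\tmissense"), tsv)
#' readAllelicCounts(tsv)
#' @export
readAllelicCounts <- function(path, format = c("tsv", "vcf"),
                              assay = NULL, mutationClass = "missense") {
  format <- match.arg(format)
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  if (format == "tsv") .readCountsTsv(path) else {
    .readCountsVcf(path, assay = assay, mutationClass = mutationClass)
  }
}

.readCountsTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.COUNT_COLUMNS, colnames(df))
  stopIfNot(length(missing_cols) == 0,
            paste("missing required column(s):",
                  paste(missing_cols, collapse = ", ")))
  wt <- suppressWarnings(as.integer(df$wt_reads))
  mut <- suppressWarnings(as.integer(df$mut_reads))
  pos <- suppressWarnings(as.integer(df$pos))
  problems <- character(0)
  bad <- which(is.na(wt) | is.na(mut) | wt < 0 | mut < 0)
  if (length(bad))
    problems <- c(problems, sprintf("row %d: invalid read counts", bad))
  bad_assay <- which(!df$assay %in% .ASSAY_LEVELS)
  if (length(bad_assay))
    problems <- c(problems, sprintf("row %d: unknown assay label '%s'",
                                    bad_assay, df$assay[bad_assay]))
  bad_pos <- which(is.na(pos) | pos < 1)
  if (length(bad_pos))
    problems <- c(problems, sprintf("row %d: invalid position", bad_pos))
  stopIfNot(length(problems) == 0,
            paste0("malformed rows in ", path, ":\n  ",
                   paste(problems, collapse = "\n  ")))
  AllelicCounts(data.frame(
    sample_id = df$sample_id, chrom = df$chrom, pos = pos,
    assay = df$assay, wt_reads = wt, mut_reads = mut,
    mutation_class = df$mutation_class, stringsAsFactors = FALSE))
}

.readCountsVcf <- function(path, assay = NULL, mutationClass = "missense") {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  stopIfNot(!is.null(ad), "VCF has no per-sample AD FORMAT field")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  n_var <- nrow(vcf)
  samples <- colnames(vcf)
  assay_label <- if ("ASSAY" %in% colnames(info)) {
    as.character(info$ASSAY)
  } else {
    stopIfNot(!is.null(assay), "no ASSAY INFO field; supply `assay`")
    rep(assay, n_var)
  }
  class_label <- if ("CLASS" %in% colnames(info)) {
    ifelse(as.character(info$CLASS) == "missense", "missense", "other")
  } else rep(mutationClass, n_var)
  getAD <- if (is.array(ad) && length(dim(ad)) == 3L) {
    function(i, j) ad[i, j, ]
  } else {
    function(i, j) ad[[(j - 1L) * n_var + i]]   # list-matrix, column-major
  }
  rows <- list()
  for (i in seq_len(n_var)) {
    for (j in seq_along(samples)) {
      depths <- getAD(i, j)
      if (is.null(depths) || length(depths) < 2L || anyNA(depths)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[j],
        chrom = as.character(GenomicRanges::seqnames(rr))[i],
        pos = GenomicRanges::start(rr)[i],
        assay = assay_label[i],
        wt_reads = depths[1L], mut_reads = depths[2L],
        mutation_class = class_label[i], stringsAsFactors = FALSE)
    }
  }
  stopIfNot(length(rows) > 0, "no usable AD records in VCF")
  AllelicCounts(do.call(rbind, rows))
}

#' Write allelic counts to a TSV table
#'
#' Writes the table in the same dialect [readAllelicCounts()] reads,
#' so that a write-then-read round trip reproduces the records exactly.
#'
#' @param x an [AllelicCounts-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAllelicCounts <- function(x, path) {
  stopIfNot(is(x, "AllelicCounts"), "x must be an AllelicCounts object")
  utils::write.table(as.data.frame(x)[, .COUNT_COLUMNS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter tumor samples for allelic-imbalance analysis
#'
#' Applies the two quality filters used before imbalance inference:
#' keep a (sample, locus) pair only when (1) the mutation is missense
#' and (2) the summed depth of both alleles is at least `minReads` in
#' the DNA assay and at least `minReads` in the RNA assay. Pairs
#' missing one assay are excluded. Every exclusion is recorded with a
#' machine-readable reason code in `metadata(x)$exclusions`
#' (codes: `not_missense`, `low_dna_depth`, `low_rna_depth`,
#' `missing_dna`, `missing_rna`).
#'
#' A sample carrying several missense mutations yields one retained
#' locus per mutation by default; `collapse = "max-depth"` keeps only
#' the locus with the highest combined DNA+RNA depth per sample.
#'
#' @param x an [AllelicCounts-class] object.
#' @param minReads minimum summed read depth per assay (default 30).
#' @param collapse `"none"` (default) or `"max-depth"`.
#' @return an [AllelicCounts-class] object restricted to retained
#'   (sample, locus) pairs, with the exclusion log in
#'   `metadata(..)$exclusions`.
#' @examples
#' x <- AllelicCounts(data.frame(
#'   sample_id = "S1", chrom = "chr3", pos = 1L,
#'   assay = c("DNA", "RNA"), wt_reads = c(20L, 40L),
#'   mut_reads = c(15L, 10L), mutation_class = "missense"))
#' filterSamples(x)        # retained: depths 35 and 50
#' @export
filterSamples <- function(x, minReads = 30, collapse = c("none", "max-depth")) {
  stopIfNot(is(x, "AllelicCounts"), "x must be an AllelicCounts object")
  collapse <- match.arg(collapse)
  df <- as.data.frame(x)
  df$key <- paste(df$sample_id, df$chrom, df$pos, sep = "\r")
  keys <- unique(df$key)
  reasons <- character(0); excluded_keys <- character(0)
  keep <- character(0)
  depth_total <- numeric(0)
  for (k in keys) {
    sub <- df[df$key == k, ]
    dna <- sub[sub$assay == "DNA", ]
    rna <- sub[sub$assay == "RNA", ]
    reason <- NULL
    if (!all(sub$mutation_class == "missense")) reason <- "not_missense"
    else if (nrow(dna) == 0) reason <- "missing_dna"
    else if (nrow(rna) == 0) reason <- "missing_rna"
    else if (sum(dna$wt_reads + dna$mut_reads) < minReads) reason <- "low_dna_depth"
    else if (sum(rna$wt_reads + rna$mut_reads) < minReads) reason <- "low_rna_depth"
    if (is.null(reason)) {
      keep <- c(keep, k)
      depth_total <- c(depth_total, sum(sub$wt_reads + sub$mut_reads))
    } else {
      excluded_keys <- c(excluded_keys, k)
      reasons <- c(reasons, reason)
    }
  }
  if (collapse == "max-depth" && length(keep)) {
    parts <- do.call(rbind, strsplit(keep, "\r", fixed = TRUE))
    by_sample <- split(seq_along(keep), parts[, 1])
    chosen <- vapply(by_sample, function(idx) idx[which.max(depth_total[idx])],
                     integer(1))
    dropped <- setdiff(seq_along(keep), chosen)
    if (length(dropped)) {
      excluded_keys <- c(excluded_keys, keep[dropped])
      reasons <- c(reasons, rep("collapsed_secondary_locus", length(dropped)))
    }
    keep <- keep[chosen]
  }
  out <- AllelicCounts(df[df$key %in% keep, .COUNT_COLUMNS])
  excl <- if (length(excluded_keys)) {
    parts <- do.call(rbind, strsplit(excluded_keys, "\r", fixed = TRUE))
    data.frame(sample_id = parts[, 1], chrom = parts[, 2],
               pos = as.integer(parts[, 3]), reason = reasons,
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), reason = character(0))
  }
  metadata(out)$exclusions <- excl
  metadata(out)$min_reads <- minReads
  out
}

#' Read a clinical covariate table
#'
#' Reads a CSV/TSV of per-sample clinical covariates: hormone-receptor
#' statuses (`er_status`, `pr_status`, `her2_status`: "positive",
#' "negative" or NA), ordinal `grade`, `size`, `stage`, subtype labels
#' (`pam50`, `intclust`), and survival columns (`os_time`, `os_event`,
#' `dss_time`, `dss_event`; times in years, events 0/1). Only
#' `sample_id` is required; other columns are validated when present.
#'
#' @param path path to a delimited file (delimiter sniffed from the
#'   extension: `.csv` comma, otherwise tab).
#' @return a `data.frame` of clinical records.
#' @export
readClinical <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  stopIfNot("sample_id" %in% colnames(df), "clinical table needs sample_id")
  for (st in c("er_status", "pr_status", "her2_status")) {
    if (st %in% colnames(df))
      stopIfNot(all(df[[st]] %in% c("positive", "negative", NA)),
                sprintf("%s must be 'positive', 'negative' or NA", st))
  }
  for (tm in c("os_time", "dss_time")) {
    ev <- sub("_time", "_event", tm)
    if (tm %in% colnames(df)) {
      stopIfNot(all(is.na(df[[tm]]) | df[[tm]] >= 0),
                sprintf("%s must be non-negative", tm))
      if (ev %in% colnames(df))
        stopIfNot(all(is.na(df[[ev]]) | df[[ev]] %in% 0:1),
                  sprintf("%s must be 0/1", ev))
    }
  }
  df
}
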