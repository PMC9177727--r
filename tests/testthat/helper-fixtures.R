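# Fixtures built in code: small count tables and AE matrices.

makeCounts <- function(...) {
  rows <- list(...)
  AllelicCounts(do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], chrom = "chr3", pos = as.integer(r[[2]]),
               assay = r[[3]], wt_reads = as.integer(r[[4]]),
               mut_reads = as.integer(r[[5]]),
               mutation_class = if (length(r) > 5) r[[6]] else "missense",
               stringsAsFactors = FALSE)
  })))
}

countRow <- function(sample, pos, assay, wt, mut, class = "missense") {
  list(sample, pos, assay, wt, mut, class)
}

# A tiny AEMatrix: genotypes and log ratios given as variant-by-sample
# matrices; positions default to an evenly spaced grid on chr3.
makeAEMatrix <- function(genotype, aeTrue = NULL, intensity = NULL,
                         pos = NULL, noise = 0) {
  nv <- nrow(genotype); ns <- ncol(genotype)
  if (is.null(rownames(genotype)))
    rownames(genotype) <- sprintf("v%02d", seq_len(nv))
  if (is.null(colnames(genotype)))
    colnames(genotype) <- sprintf("s%02d", seq_len(ns))
  if (is.null(aeTrue)) aeTrue <- matrix(0, nv, ns)
  if (is.null(intensity)) intensity <- rep(11, nv)
  if (is.null(pos)) pos <- 1000000L + 10000L * seq_len(nv)
  base <- ifelse(genotype == "AA", 2.5, ifelse(genotype == "BB", -2.5, 0))
  dna <- base + matrix(stats::rnorm(nv * ns, 0, noise), nv, ns)
  rna <- base + aeTrue + matrix(stats::rnorm(nv * ns, 0, noise), nv, ns)
  dimnames(dna) <- dimnames(rna) <- dimnames(genotype)
  AEMatrix(rna, dna, genotype,
           data.frame(variant_id = rownames(genotype), chrom = "chr3",
                      pos = pos, allele_a = "A", allele_b = "C",
                      stringsAsFactors = FALSE),
           intensity)
}

# Genotype row with a prescribed number of het and hom samples.
gtRow <- function(nHet, nAA, nBB = 0) c(rep("AB", nHet), rep("AA", nAA), rep("BB", nBB))

writeTempTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
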