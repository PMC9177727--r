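#' Run the full allelic-imbalance pipeline on one cohort
#'
#' Orchestrates the stages end to end: read (or simulate) allelic
#' counts and clinical data, apply the sample filters, infer the
#' alpha/beta/gamma profiles, decompose the variance of net allelic
#' expression, test mutant-preference prevalence among
#' gamma-imbalanced tumors, categorize tumors by their gamma call,
#' and run the survival comparison. All stage outputs are written
#' under `outDir` together with a `manifest.json` recording every
#' parameter and filter count; a rerun with the same inputs and seed
#' reproduces the outputs exactly.
#'
#' @param countsPath path to an allelic-counts TSV (see
#'   [readAllelicCounts()]); `NULL` to simulate a cohort instead.
#' @param clinicalPath path to a clinical table ([readClinical()]);
#'   ignored when simulating (the simulated clinical table is used).
#' @param outDir output directory (created if missing).
#' @param config a [SimulationConfig-class] used when
#'   `countsPath` is `NULL`.
#' @param spec a [PosteriorSpec-class] for the inference stage.
#' @param minReads depth filter (default 30).
#' @param level credible level (default 0.89).
#' @return invisibly, a list with `profiles`, `decomposition`,
#'   `correlations`, `quadrants`, `prevalence`, `categories`,
#'   `survival` (NULL without clinical data), and `manifest`.
#' @export
runPipeline <- function(countsPath = NULL, clinicalPath = NULL,
                        outDir = tempfile("aei_run_"),
                        config = simulationConfig(),
                        spec = posteriorSpec(), minReads = 30,
                        level = 0.89) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  clinical <- NULL
  if (is.null(countsPath)) {
    sim <- simulateCohort(config)
    counts <- sim$counts
    clinical <- sim$clinical
    utils::write.table(sim$truth, file.path(outDir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeAllelicCounts(counts, file.path(outDir, "counts.tsv"))
    utils::write.table(clinical, file.path(outDir, "clinical.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    source_desc <- list(type = "simulated",
                        seed = config@seed, n_samples = config@nSamples)
  } else {
    counts <- readAllelicCounts(countsPath, format = "tsv")
    if (!is.null(clinicalPath)) clinical <- readClinical(clinicalPath)
    source_desc <- list(type = "files", counts = countsPath,
                        clinical = clinicalPath)
  }
  filtered <- filterSamples(counts, minReads = minReads)
  excl <- metadata(filtered)$exclusions
  profiles <- profileCohort(filtered, spec = spec, level = level)
  writeProfiles(profiles, file.path(outDir, "profiles.tsv"))
  pdf_ <- as.data.frame(profiles)
  decomp <- varianceDecomposition(pdf_$beta_map, pdf_$gamma_map)
  corr <- tryCatch(ratioCorrelations(pdf_$alpha_map, pdf_$beta_map,
                                     pdf_$gamma_map),
                   error = function(e) NULL)
  quad <- quadrantCounts(profiles)
  prev <- gammaPrevalence(profiles, level = level)
  categories <- categorizeGamma(profiles)
  surv <- NULL
  if (!is.null(clinical) &&
      all(c("os_time", "os_event") %in% colnames(clinical))) {
    d <- merge(categories, clinical, by = "sample_id")
    if (length(unique(d$category)) >= 2 && sum(d$os_event) > 0) {
      surv <- tryCatch(
        kmLogrank(d$os_time, d$os_event, d$category),
        error = function(e) NULL)
    }
  }
  report <- list(
    decomposition = decomp, correlations = corr, quadrants = quad,
    prevalence = prev,
    survival = if (!is.null(surv))
      list(logrank_p = surv$logrank_p,
           medians = as.list(surv$medians),
           n_events = as.list(surv$n_events)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  manifest <- list(
    package = "cisAEI",
    version = as.character(utils::packageVersion("cisAEI")),
    source = source_desc,
    parameters = list(min_reads = minReads, level = level,
                      prior_a = spec@priorA, prior_b = spec@priorB,
                      n_draws = spec@nDraws, seed = spec@seed),
    filter_counts = list(
      input_pairs = nrow(excl) + length(unique(paste(
        as.data.frame(filtered)$sample_id, as.data.frame(filtered)$pos))),
      retained_pairs = nrow(profiles),
      excluded = as.list(table(excl$reason))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profiles = profiles, decomposition = decomp,
                 correlations = corr, quadrants = quad, prevalence = prev,
                 categories = categories, survival = surv,
                 manifest = manifest))
}
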