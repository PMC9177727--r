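#' Categorize tumors by their gamma imbalance call
#'
#' Maps each profile's gamma call to one of three groups used in the
#' clinical analyses: `gamma_mut` (cis-regulatory preference for the
#' mutant allele), `gamma_wt` (preference for the wild-type allele)
#' or `gamma_balanced`. The category is a pure function of the gamma
#' credible-interval call; profiles with a missing call are dropped
#' with a reason.
#'
#' @param profiles a [SampleProfiles-class] object (or a `data.frame`
#'   with `sample_id` and `gamma_call` columns).
#' @return a `data.frame` with `sample_id`, `chrom`, `pos` (when
#'   present) and `category`; dropped rows are attached as the
#'   `"dropped"` attribute.
#' @export
categorizeGamma <- function(profiles) {
  df <- as.data.frame(profiles)
  stopIfNot(all(c("sample_id", "gamma_call") %in% colnames(df)),
            "profiles need sample_id and gamma_call")
  ok <- !is.na(df$gamma_call) & df$gamma_call %in% c("balanced", "mutant", "wildtype")
  out <- df[ok, intersect(c("sample_id", "chrom", "pos"), colnames(df)),
            drop = FALSE]
  out$category <- c(balanced = "gamma_balanced", mutant = "gamma_mut",
                    wildtype = "gamma_wt")[df$gamma_call[ok]]
  rownames(out) <- NULL
  dropped <- df[!ok, "sample_id", drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "missing_gamma_call"
  attr(out, "dropped") <- dropped
  out
}

#' Rank-based comparison of imbalance ratios across clinical groups
#'
#' Compares MAP ratio values between the levels of a clinical
#' covariate: Wilcoxon rank-sum test with continuity correction for
#' two levels, Kruskal-Wallis rank-sum test for more. Samples with a
#' missing covariate or non-finite ratio are dropped.
#'
#' @param values numeric vector of per-sample MAP ratio values.
#' @param groups vector (factor, character or ordinal) of covariate
#'   levels, parallel to `values`.
#' @param minGroup minimum samples per level (default 2); smaller
#'   levels are dropped.
#' @return a list with `statistic`, `p_value`, `method` and
#'   `group_sizes`.
#' @examples
#' groupComparison(c(1, 2, 3, 6, 7, 8), rep(c("neg", "pos"), each = 3))
#' @export
groupComparison <- function(values, groups, minGroup = 2) {
  stopIfNot(length(values) == length(groups), "values and groups must be paired")
  ok <- is.finite(values) & !is.na(groups)
  v <- values[ok]; g <- as.character(groups[ok])
  sizes <- table(g)
  usable <- names(sizes)[sizes >= minGroup]
  stopIfNot(length(usable) >= 2, "need at least 2 groups with enough samples")
  sel <- g %in% usable
  v <- v[sel]; g <- factor(g[sel])
  if (nlevels(g) == 2) {
    sp <- split(v, g)
    ht <- suppressWarnings(stats::wilcox.test(sp[[1]], sp[[2]], correct = TRUE))
    method <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(v, g)
    method <- "kruskal-wallis"
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = method, group_sizes = as.list(table(g)))
}

#' Ratio-by-covariate associations with per-study BH adjustment
#'
#' Runs [groupComparison()] of one ratio against each listed clinical
#' covariate and adjusts the resulting P values with the
#' Benjamini-Hochberg method. Adjustment is per study: call this once
#' per cohort. Significance at `q <= bhAlpha`.
#'
#' @param profiles a [SampleProfiles-class] object.
#' @param clinical a clinical `data.frame` with a `sample_id` column
#'   (see [readClinical()]).
#' @param covariates character vector of clinical column names.
#' @param ratio which MAP to compare: "gamma" (default) or "alpha".
#' @param bhAlpha FDR cutoff (default 0.05).
#' @return a `data.frame` with one row per covariate: `covariate`,
#'   `statistic`, `p_value`, `q_value`, `significant`, `method`,
#'   `n_used`.
#' @export
clinicalAssociations <- function(profiles, clinical, covariates,
                                 ratio = c("gamma", "alpha"),
                                 bhAlpha = 0.05) {
  ratio <- match.arg(ratio)
  df <- as.data.frame(profiles)
  col <- paste0(ratio, "_map")
  merged <- merge(df[, c("sample_id", col)], clinical, by = "sample_id")
  rows <- lapply(covariates, function(cv) {
    stopIfNot(cv %in% colnames(merged),
              sprintf("covariate '%s' absent from clinical table", cv))
    res <- tryCatch(groupComparison(merged[[col]], merged[[cv]]),
                    error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(covariate = cv, statistic = NA_real_,
                        p_value = NA_real_, method = NA_character_,
                        n_used = 0L, stringsAsFactors = FALSE))
    }
    data.frame(covariate = cv, statistic = res$statistic,
               p_value = res$p_value, method = res$method,
               n_used = sum(unlist(res$group_sizes)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$significant <- !is.na(out$q_value) & out$q_value <= bhAlpha
  out[, c("covariate", "statistic", "p_value", "q_value", "significant",
          "method", "n_used")]
}

#' Kaplan-Meier curves and log-rank test by gamma category
#'
#' Product-limit survival estimates per category with the log-rank
#' test across categories, per-group median survival (undefined when
#' a curve never crosses 0.5) and a numbers-at-risk table on a yearly
#' grid.
#'
#' @param times numeric survival/censoring times (years, >= 0).
#' @param events 0/1 event indicators (1 = death).
#' @param categories group labels, e.g. from [categorizeGamma()].
#' @param riskTimes time points for the at-risk table (default
#'   `0, 2, ..., 14` years).
#' @return a list with `fit` (the `survfit` object), `logrank_p`,
#'   `medians` (named per group, NA when undefined), `n_events`
#'   (named), and `at_risk` (groups x times matrix).
#' @export
kmLogrank <- function(times, events, categories,
                      riskTimes = seq(0, 14, by = 2)) {
  stopIfNot(length(times) == length(events) &&
              length(times) == length(categories),
            "times, events, categories must be paired")
  ok <- !is.na(times) & !is.na(events) & !is.na(categories)
  d <- data.frame(time = times[ok], event = events[ok],
                  group = factor(categories[ok]))
  stopIfNot(all(d$time >= 0), "negative survival times")
  stopIfNot(nlevels(d$group) >= 2, "need at least 2 groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  logrank_p <- if (sum(d$event) == 0) NA_real_ else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    stats::pchisq(sd_$chisq, df = nlevels(d$group) - 1, lower.tail = FALSE)
  }
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(levels(d$group), names(tab)))
  medians <- tab[, "median"]
  names(medians) <- sub("^group=", "", rownames(tab))
  n_events <- tab[, "events"]
  names(n_events) <- names(medians)
  sf <- summary(fit, times = riskTimes, extend = TRUE)
  strata <- sub("^group=", "", as.character(sf$strata))
  at_risk <- matrix(sf$n.risk, nrow = nlevels(d$group), byrow = TRUE,
                    dimnames = list(unique(strata), riskTimes))
  list(fit = fit, logrank_p = logrank_p, medians = medians,
       n_events = n_events, at_risk = at_risk)
}

#' Multivariate Cox proportional-hazards model
#'
#' Fits a Cox model of survival on the gamma category (factor with
#' `gamma_balanced` as the reference level) adjusted for clinical
#' covariates, reporting hazard ratios with Wald 95% confidence
#' intervals. Non-convergence or likely separation (a coefficient
#' standard error above 100 on the log-HR scale) is flagged in the
#' output rather than silently dropped.
#'
#' @param data a `data.frame` holding the time/event columns, a
#'   `category` column, and the covariates.
#' @param timeCol,eventCol names of the survival time and 0/1 event
#'   columns.
#' @param covariates character vector of adjustment covariate column
#'   names (may be empty).
#' @param minEvents minimum number of events required (default 10).
#' @return a `data.frame` with one row per model term: `term`, `hr`,
#'   `ci_low`, `ci_high` (95% Wald), `p_value`, `flag`
#'   (NA, "non_convergence" or "possible_separation").
#' @export
coxMultivariate <- function(data, timeCol = "os_time", eventCol = "os_event",
                            covariates = character(0), minEvents = 10) {
  stopIfNot(all(c(timeCol, eventCol, "category") %in% colnames(data)),
            "data needs time, event and category columns")
  d <- data[stats::complete.cases(data[, c(timeCol, eventCol, "category",
                                           covariates)]), , drop = FALSE]
  stopIfNot(sum(d[[eventCol]]) >= minEvents,
            sprintf("fewer than %d events", minEvents))
  lev <- unique(d$category)
  d$category <- factor(d$category,
                       levels = c("gamma_balanced",
                                  setdiff(sort(lev), "gamma_balanced")))
  for (cv in covariates) {
    if (is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
    vals <- d[[cv]]
    stopIfNot(length(unique(vals[!is.na(vals)])) > 1,
              sprintf("constant covariate '%s'", cv))
  }
  rhs <- paste(c("category", covariates), collapse = " + ")
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s",
                                   timeCol, eventCol, rhs))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  flag <- rep(NA_character_, nrow(co))
  flag[co[, "se(coef)"] > 100] <- "possible_separation"
  if (warned) flag[is.na(flag)] <- "non_convergence"
  data.frame(term = rownames(co), hr = co[, "exp(coef)"],
             ci_low = sm$conf.int[, "lower .95"],
             ci_high = sm$conf.int[, "upper .95"],
             p_value = co[, "Pr(>|z|)"], flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}
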