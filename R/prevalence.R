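#' Exact binomial test for mutant-allele preference
#'
#' Among tumors whose gamma (cis-regulatory) ratio is significantly
#' imbalanced, tests whether mutant-preferring tumors predominate:
#' k successes (mutant-preferring) out of n imbalanced tumors against
#' a null proportion p0. The two-sided P value is the exact
#' minimum-likelihood binomial P (the sum of probabilities of all
#' outcomes no more likely than the observed one), and the interval
#' is the exact Clopper-Pearson interval at the requested level
#' (default 89%).
#'
#' @param k number of mutant-preferring tumors (successes).
#' @param n number of gamma-imbalanced tumors (trials).
#' @param p0 null proportion (default 0.5).
#' @param level confidence level (default 0.89).
#' @return a list with `k`, `n`, `estimate` (k/n), `ci_low`, `ci_high`,
#'   `p_value` and `level`.
#' @examples
#' mutantPreferenceTest(26, 26)   # P ~ 3e-8, CI [0.894, 1]
#' mutantPreferenceTest(19, 21)   # P ~ 2e-4, CI [0.734, 0.982]
#' @export
mutantPreferenceTest <- function(k, n, p0 = 0.5, level = 0.89) {
  stopIfNot(length(k) == 1 && length(n) == 1, "k and n must be scalars")
  stopIfNot(n >= 1 && k >= 0 && k <= n, "need 0 <= k <= n, n >= 1")
  stopIfNot(level > 0 && level < 1, "level must be in (0, 1)")
  p <- stats::binom.test(k, n, p = p0)$p.value
  alpha <- 1 - level
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  list(k = as.integer(k), n = as.integer(n), estimate = k / n,
       ci_low = lo, ci_high = hi, p_value = p, level = level)
}

#' Mutant-preference prevalence from cohort profiles
#'
#' Convenience wrapper: restricts a cohort to gamma-imbalanced tumors
#' (gamma CI excluding zero) and runs [mutantPreferenceTest()] with
#' the mutant-preferring tumors as successes.
#'
#' @param profiles a [SampleProfiles-class] object.
#' @param p0,level passed to [mutantPreferenceTest()].
#' @return the [mutantPreferenceTest()] result list, or `NULL` (with
#'   a message) when no tumor is gamma-imbalanced.
#' @export
gammaPrevalence <- function(profiles, p0 = 0.5, level = 0.89) {
  df <- as.data.frame(profiles)
  imb <- df$gamma_call != "balanced"
  n <- sum(imb)
  if (n == 0) {
    message("no gamma-imbalanced tumors; prevalence test not run")
    return(NULL)
  }
  mutantPreferenceTest(sum(df$gamma_call == "mutant"), n, p0, level)
}
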