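#' Variance decomposition of net allelic expression
#'
#' With gamma = alpha - beta, the variance of the net allelic
#' expression ratio obeys the identity
#' `Var(alpha) = Var(beta) + Var(gamma) + 2 Cov(beta, gamma)`,
#' splitting net allelic expression into a copy-number component
#' (beta), a cis-regulatory component (gamma) and their covariance.
#' The contribution of cis-regulation to the variance of net allelic
#' expression is `(Var(gamma) + Cov(beta, gamma)) / Var(alpha)`;
#' the complementary copy-number contribution is
#' `(Var(beta) + Cov(beta, gamma)) / Var(alpha)`, and the two sum to
#' one exactly.
#'
#' Pairs where either MAP is non-finite (boundary posterior modes) are
#' excluded before computing moments; the number dropped is reported.
#'
#' @param betaMaps,gammaMaps paired numeric vectors of per-sample MAP
#'   estimates (log2 units).
#' @return a list with `var_alpha`, `var_beta`, `var_gamma`,
#'   `cov_beta_gamma` (squared log2 units, n-1 denominators),
#'   `cis_contribution`, `cn_contribution`, `n_used`, `n_dropped`.
#' @examples
#' varianceDecomposition(c(1, -1, 0), c(0.5, -0.5, 0))  # contribution 1/3
#' @export
varianceDecomposition <- function(betaMaps, gammaMaps) {
  stopIfNot(length(betaMaps) == length(gammaMaps),
            "beta and gamma vectors must be paired")
  ok <- is.finite(betaMaps) & is.finite(gammaMaps)
  n_dropped <- sum(!ok)
  b <- betaMaps[ok]; g <- gammaMaps[ok]
  stopIfNot(length(b) >= 3, "need at least 3 finite (beta, gamma) pairs")
  a <- b + g
  va <- stats::var(a)
  stopIfNot(va > 0, "zero variance in net allelic expression")
  vb <- stats::var(b); vg <- stats::var(g); cbg <- stats::cov(b, g)
  list(var_alpha = va, var_beta = vb, var_gamma = vg, cov_beta_gamma = cbg,
       cis_contribution = (vg + cbg) / va,
       cn_contribution = (vb + cbg) / va,
       n_used = length(b), n_dropped = n_dropped)
}

#' Correlations of net allelic expression with its components
#'
#' Pearson correlations of alpha with beta (copy number) and alpha
#' with gamma (cis-regulation), computed on MAP point estimates.
#' Fewer than 3 finite profiles or a constant alpha vector is an
#' error; a constant component vector (e.g. gamma identically zero
#' when alpha equals beta) makes that one correlation NA.
#'
#' @param alphaMaps,betaMaps,gammaMaps paired numeric MAP vectors.
#' @return a list with `r_alpha_beta`, `r_alpha_gamma` and the squared
#'   correlations `r2_alpha_beta`, `r2_alpha_gamma`, plus `n_used`.
#' @export
ratioCorrelations <- function(alphaMaps, betaMaps, gammaMaps) {
  stopIfNot(length(alphaMaps) == length(betaMaps) &&
              length(alphaMaps) == length(gammaMaps),
            "ratio vectors must be paired")
  ok <- is.finite(alphaMaps) & is.finite(betaMaps) & is.finite(gammaMaps)
  a <- alphaMaps[ok]; b <- betaMaps[ok]; g <- gammaMaps[ok]
  stopIfNot(length(a) >= 3, "need at least 3 finite profiles")
  stopIfNot(stats::sd(a) > 0, "correlation undefined: constant alpha vector")
  # each component correlation is defined independently; a constant
  # component (e.g. gamma identically zero when alpha == beta) gives NA
  rab <- if (stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  rag <- if (stats::sd(g) > 0) stats::cor(a, g) else NA_real_
  list(r_alpha_beta = rab, r_alpha_gamma = rag,
       r2_alpha_beta = rab^2, r2_alpha_gamma = rag^2, n_used = length(a))
}

#' Beta/gamma quadrant classification of tumor profiles
#'
#' Assigns each profile to one quadrant of the (beta, gamma) plane by
#' the signs of the MAP estimates, tallying how the copy-number and
#' cis-regulatory components co-occur. Profiles with an exact zero on
#' either axis go to a separate tie bucket. Also reports the count of
#' profiles with positive alpha despite negative beta (mutant allele
#' overexpressed while in lower genomic copy number).
#'
#' @param profiles a [SampleProfiles-class] object or a `data.frame`
#'   with `alpha_map`, `beta_map` and `gamma_map` columns.
#' @return a list with integer counts
#'   `gamma_pos_beta_neg`, `gamma_pos_beta_pos`, `gamma_neg_beta_neg`,
#'   `gamma_neg_beta_pos`, `ties`, `alpha_pos_beta_neg`, and `n` (the
#'   number of finite profiles classified).
#' @export
quadrantCounts <- function(profiles) {
  df <- as.data.frame(profiles)
  ok <- is.finite(df$beta_map) & is.finite(df$gamma_map)
  b <- df$beta_map[ok]; g <- df$gamma_map[ok]; a <- df$alpha_map[ok]
  tie <- b == 0 | g == 0
  list(
    gamma_pos_beta_neg = sum(g > 0 & b < 0),
    gamma_pos_beta_pos = sum(g > 0 & b > 0),
    gamma_neg_beta_neg = sum(g < 0 & b < 0),
    gamma_neg_beta_pos = sum(g < 0 & b > 0),
    ties = sum(tie),
    alpha_pos_beta_neg = sum(is.finite(a) & a > 0 & b < 0),
    n = length(b))
}
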