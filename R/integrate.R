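#' Integrate association, network and phenotype scores
#'
#' The integrated score of gene g is its association score rescaled by a
#' bounded multiplicative coefficient:
#' `s_g = s(A)_g * (I_g + b * s(N)_g * s(P)_g)`, where the indicator
#' `I_g` is 1 for genes in the sampled risk set and `a` (0 < a < 1)
#' otherwise. The indicator puts a lower bound `a` on the coefficient so
#' network/phenotype evidence can never erase an association signal, and
#' the coefficient is at most `1 + b`.
#'
#' @param assoc Nonnegative association scores (minus log10 P-values).
#' @param net,phe Normalized network and phenotype scores in `[0, 1]`.
#' @param risk Logical (or 0/1) vector marking the sampled risk genes.
#' @param a Indicator value for non-risk genes, in (0, 1); default 0.1.
#' @param b Weight of the network-phenotype product; default 1.
#' @return A tibble with columns `assoc`, `net`, `phe`, `indicator`,
#'   `integrated`.
#' @export
integrate_scores <- function(assoc, net, phe, risk, a = 0.1, b = 1) {
  if (any(assoc < 0)) abort("association scores must be nonnegative")
  if (any(net < 0 | net > 1) || any(phe < 0 | phe > 1)) {
    abort("net and phe scores must lie in [0, 1]")
  }
  if (a <= 0 || a >= 1) abort("a must lie in (0, 1)")
  if (b < 0) abort("b must be nonnegative")
  risk <- as.logical(risk)
  indicator <- ifelse(risk, 1, a)
  tibble(
    assoc = assoc, net = net, phe = phe, indicator = indicator,
    integrated = assoc * (indicator + b * net * phe)
  )
}

# Fast internal path used inside the sampler loop (no validation, no
# tibble). `clamp` is FALSE only for the normalization-ablation mode where
# raw scores are fed through deliberately.
integrate_fast <- function(assoc, net, phe, risk_lgl, a, b) {
  assoc * (ifelse(risk_lgl, 1, a) + b * net * phe)
}

#' Attainable range of the integrated-score scaling coefficient
#'
#' Numerically explores the multiplicative coefficient
#' `I + b * s(N) * s(P)` over admissible indicator values `{a, 1}` and
#' normalized scores on a grid in `[0, 1]`, returning its minimum and
#' maximum. Under the default `(a, b) = (0.1, 1)` the range is
#' `[0.1, 2]`.
#'
#' @param a,b Integration parameters.
#' @param grid_n Number of grid points per score axis.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
scaling_coefficient_range <- function(a = 0.1, b = 1, grid_n = 101L) {
  s <- seq(0, 1, length.out = grid_n)
  prod_grid <- outer(s, s)
  coef_vals <- c(outer(c(a, 1), b * prod_grid, `+`))
  c(min = min(coef_vals), max = max(coef_vals))
}

#' Specialized scaling parameters tuned to a dataset
#'
#' Returns the dataset-specific setting in which every gene with P < 0.5
#' can compete with the strongest association signal observed:
#' `a = 0.9999999` and `b = max(assoc) / (-log10(0.5)) - 1`.
#'
#' @param assoc_scores Nonnegative association scores of the dataset.
#' @return A list with elements `a` and `b`.
#' @export
specialized_ab <- function(assoc_scores) {
  ref <- -log10(0.5)
  mx <- max(assoc_scores)
  if (mx <= ref) {
    abort("maximum association score must exceed -log10(0.5)")
  }
  list(a = 0.9999999, b = mx / ref - 1)
}

#' Predict the risk-gene percentage from association-strength sums
#'
#' Linearly interpolates the observed total association strength between
#' the null extreme (label-permuted data, 0% risk genes) and the robust
#' extreme (every gene Bonferroni-significant, 100% risk genes):
#' `x = 100 * (disease_sum - mean(null_sums)) / (robust_sum - mean(null_sums))`.
#'
#' @param disease_sum Sum of per-gene association strengths in the real
#'   data (see [association_strength_sum()]).
#' @param null_sums Numeric vector of the same sum over label-permuted
#'   null sets.
#' @param robust_sum The sum attained if every scoring gene were
#'   Bonferroni-significant (see [robust_association_sum()]).
#' @return Predicted percentage of scoring genes that are risk genes.
#' @export
predict_x <- function(disease_sum, null_sums, robust_sum) {
  null_mean <- mean(null_sums)
  if (robust_sum <= null_mean) {
    abort("robust_sum must exceed the mean null sum")
  }
  100 * (disease_sum - null_mean) / (robust_sum - null_mean)
}

#' Total association strength of a P-value set
#'
#' @param pvalues Numeric vector of gene P-values.
#' @param metric `"one_minus_p"` (sum of 1 - P) or `"minus_log10_p"`
#'   (sum of -log10 P).
#' @return The summed association strength.
#' @export
association_strength_sum <- function(pvalues,
                                     metric = c("one_minus_p",
                                                "minus_log10_p")) {
  metric <- match.arg(metric)
  switch(metric,
    one_minus_p = sum(1 - pvalues),
    minus_log10_p = sum(-log10(pvalues))
  )
}

#' Robust (fully significant) association-strength bound
#'
#' The total association strength if every one of `m` scoring genes had a
#' P-value exactly at the per-gene Bonferroni threshold `alpha / m`.
#'
#' @param m Number of scoring genes.
#' @param alpha Family-wise significance level (default 0.05).
#' @inheritParams association_strength_sum
#' @return The robust sum under the chosen metric.
#' @export
robust_association_sum <- function(m, alpha = 0.05,
                                   metric = c("one_minus_p",
                                              "minus_log10_p")) {
  metric <- match.arg(metric)
  switch(metric,
    one_minus_p = m * (1 - alpha / m),
    minus_log10_p = m * (-log10(alpha / m))
  )
}
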