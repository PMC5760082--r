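#' Rank-against-risk-genes score normalization
#'
#' Normalizes raw network or phenotype scores to `[0, 1]` by the fraction
#' of currently sampled risk genes whose raw score is strictly lower than
#' the raw score of the gene being normalized. Ties contribute nothing.
#' A sampled risk gene is normalized against all sampled risk genes,
#' itself included.
#'
#' @param raw Finite numeric vector of raw scores over the gene universe.
#' @param risk_idx Integer indices (into `raw`) of the sampled risk genes.
#' @return Numeric vector in `[0, 1]`, same length as `raw`.
#' @examples
#' normalize_fn(c(0.8, 0.1, 0.3, 0.5, 0.9), risk_idx = 2:5)
#' @export
normalize_fn <- function(raw, risk_idx) {
  if (length(risk_idx) == 0L) abort("risk set must be non-empty")
  if (!all(is.finite(raw))) abort("raw scores must be finite")
  count_strictly_below(raw, raw[risk_idx]) / length(risk_idx)
}

#' Min-max score normalization
#'
#' Linearly rescales raw scores to `[0, 1]`:
#' `(raw - min(raw)) / (max(raw) - min(raw))`. If all values are equal the
#' output is all zeros (documented convention).
#'
#' @param raw Finite numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
normalize_minmax <- function(raw) {
  if (!all(is.finite(raw))) abort("raw scores must be finite")
  rng <- range(raw)
  if (rng[1L] == rng[2L]) return(rep(0, length(raw)))
  (raw - rng[1L]) / (rng[2L] - rng[1L])
}
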