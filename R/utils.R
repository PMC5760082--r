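# Shared internal helpers.

# Half-up rounding; base round() rounds half to even, which is not what we
# want when sizing the sampled risk-gene set.
round_half_up <- function(x) floor(x + 0.5)

# Number of sampled risk genes for m scoring genes and an assumed risk
# percentage x, clamped to [min_n, m - 1].
risk_set_size <- function(m, x, min_n = 30L) {
  n <- round_half_up(m * x / 100)
  n <- max(n, min_n)
  n <- min(n, m - 1L)
  as.integer(n)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Strict-count rank normalization support: number of elements of `ref`
# strictly smaller than each element of `x`.
count_strictly_below <- function(x, ref) {
  findInterval(x, sort(ref), left.open = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
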