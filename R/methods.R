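#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.rvp_fit <- function(x, ...) {
  cat(sprintf("Integrated risk-gene prioritization (%s mode)\n",
              x$params$mode %||% "burden-only"))
  cat(sprintf("  %d scoring genes; %s sampled risk genes per iteration\n",
              x$m, ifelse(is.na(x$n), "no", x$n)))
  if (x$n_iterations > 0L) {
    cat(sprintf("  %d iterations (%d post burn-in); converged: %s\n",
                x$n_iterations, x$post_burnin_iterations, x$converged))
  }
  cat("Top genes:\n")
  print(head(score_table(x), 5L))
  invisible(x)
}

#' Tidy per-gene results of a prioritization fit
#'
#' @param x An `rvp_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene`, `final_score`, `rank`,
#'   `pvalue`, `assoc_score`, `avg_net`, `avg_phe`, ranked by decreasing
#'   final score with alphabetical tie-breaking.
#' @exportS3Method generics::tidy
tidy.rvp_fit <- function(x, ...) {
  score_table(x)
}

#' One-row summary of a prioritization fit
#'
#' @param x An `rvp_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `m`, `n`, `n_iterations`,
#'   `post_burnin_iterations`, `converged`, `mode`, `sum_final_scores`.
#' @exportS3Method generics::glance
glance.rvp_fit <- function(x, ...) {
  tibble(
    m = x$m,
    n = x$n,
    n_iterations = x$n_iterations,
    post_burnin_iterations = x$post_burnin_iterations,
    converged = x$converged,
    mode = x$params$mode %||% "burden-only",
    sum_final_scores = sum(x$scores$final_score)
  )
}

#' Plot final scores against gene rank
#'
#' Scatter of per-gene final scores (sampling rates) by rank, colored by
#' the underlying association score; useful for eyeballing how far
#' network/phenotype evidence reshuffles the burden-test ordering.
#'
#' @param object An `rvp_fit` object.
#' @param top Number of top-ranked genes to display (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rvp_fit <- function(object, top = Inf, ...) {
  tab <- score_table(object)
  tab <- tab[tab$rank <= top, , drop = FALSE]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$rank, y = .data$final_score,
                                    color = .data$assoc_score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_viridis_c(name = "-log10 P") +
    ggplot2::labs(x = "Gene rank", y = "Final score (sampling rate)") +
    ggplot2::theme_minimal()
}

#' Plot sampling-rate convergence across records
#'
#' Shows the mean absolute change of per-gene sampling rates between
#' consecutive records, on a log scale, with the convergence threshold.
#'
#' @param fit An `rvp_fit` with a record history.
#' @return A ggplot object.
#' @export
plot_convergence <- function(fit) {
  rh <- fit$record_history
  if (is.null(rh) || nrow(rh) < 2L) {
    abort("fit has fewer than two rate records")
  }
  diffs <- rowMeans(abs(rh[-1L, , drop = FALSE] - rh[-nrow(rh), , drop = FALSE]))
  tab <- tibble(record = seq_along(diffs) + 1L, mean_abs_change = diffs)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$record,
                                    y = .data$mean_abs_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = fit$params$tol, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Record", y = "Mean |rate change|") +
    ggplot2::theme_minimal()
}
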