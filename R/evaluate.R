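#' Count risk genes among the top-k scored genes
#'
#' Ranks genes by score (descending, ties broken alphabetically by gene
#' symbol) and counts how many of the first `k` belong to the risk set —
#' the benchmark metric for prioritization performance.
#'
#' @param scores A tibble with columns `gene` and a score column
#'   (`final_score`, or the column named by `score_col`), or an
#'   `rvp_fit`.
#' @param risk_genes Character vector of true risk genes.
#' @param k Number of top genes to consider (default 50).
#' @param score_col Name of the score column.
#' @return Integer count of risk genes in the top k.
#' @export
evaluate_top_k <- function(scores, risk_genes, k = 50L,
                           score_col = "final_score") {
  if (inherits(scores, "rvp_fit")) scores <- scores$scores
  scores <- as_tibble(scores)
  if (k > nrow(scores)) abort("k exceeds the number of scored genes")
  ord <- order(-scores[[score_col]], scores$gene)
  top <- scores$gene[ord][seq_len(k)]
  sum(top %in% risk_genes)
}

#' Benchmark integration arms on a synthetic world
#'
#' Scores one synthetic world under any subset of the four integration
#' arms — burden-only ranking, network-only, phenotype-only, and full
#' integration — and reports the top-k risk-gene counts.
#'
#' @param world A `synthetic_world` from [simulate_world()].
#' @param params A [sampler_params()] list used for the sampler arms.
#' @param arms Character vector of arms to run.
#' @param k Top-k cutoff (default 50).
#' @param seed Optional seed applied to each sampler arm.
#' @return A tibble with columns `arm` and `top_k_count`.
#' @export
benchmark_arms <- function(world,
                           params = sampler_params(min_n = 1L),
                           arms = c("burden-only", "network-only",
                                    "phenotype-only", "full"),
                           k = 50L, seed = NULL) {
  purrr::map_dfr(arms, function(arm) {
    p <- params
    p$seed <- seed
    fit <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                            mode = arm, params = p, quiet = TRUE)
    tibble(arm = arm,
           top_k_count = evaluate_top_k(fit, world$risk_genes, k = k))
  })
}

#' Negative control: rerun scoring with permuted association signals
#'
#' Each trial randomly re-assigns the observed P-values to genes (a
#' uniform permutation), reruns the sampler, and records the sorted
#' scores of the top `k` genes. Comparing the unpermuted run's top scores
#' against the per-rank null mean and standard deviation shows how much
#' of the scoring is driven by genuine association signal rather than by
#' network/phenotype structure alone.
#'
#' @param pvalues Tibble with columns `gene` and `pvalue`.
#' @param network An undirected [igraph::graph] or `network_model`.
#' @param phenotypes Incidence matrix or `phenotype_model`.
#' @param params A [sampler_params()] list.
#' @param n_trials Number of permutation trials.
#' @param k Number of top ranks summarized (default 100).
#' @param seed RNG seed; the same seed reproduces the same summaries.
#' @return A tibble with columns `rank`, `mean_score`, `sd_score`
#'   describing the null distribution of sorted top-k scores; the full
#'   trials-by-rank matrix is attached as attribute `"trials"`.
#' @export
negative_control <- function(pvalues, network, phenotypes,
                             params = sampler_params(min_n = 1L),
                             n_trials = 10L, k = 100L, seed = NULL) {
  if (n_trials < 1L) abort("n_trials must be >= 1")
  if (!is.null(seed)) withr::local_seed(seed)
  pvalues <- as_tibble(pvalues)
  k <- min(k, nrow(pvalues))
  trial_tops <- vapply(seq_len(n_trials), function(tr) {
    perm <- pvalues
    perm$pvalue <- sample(pvalues$pvalue)
    fit <- prioritize_genes(perm, network, phenotypes, mode = "full",
                            params = params, quiet = TRUE)
    sort(fit$scores$final_score, decreasing = TRUE)[seq_len(k)]
  }, numeric(k))
  trial_tops <- base::t(trial_tops) # trials x rank
  out <- tibble(
    rank = seq_len(k),
    mean_score = colMeans(trial_tops),
    sd_score = apply(trial_tops, 2L, sd)
  )
  attr(out, "trials") <- trial_tops
  out
}
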