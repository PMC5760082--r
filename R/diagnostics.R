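#' Test whether a gene set is over-connected in a network
#'
#' Counts the edges with both endpoints in `gene_set` and compares the
#' count against a null distribution obtained by drawing same-size gene
#' sets uniformly at random from the network's nodes. The empirical
#' P-value uses the standard add-one correction
#' `(1 + #{null >= observed}) / (iterations + 1)`.
#'
#' @param graph An undirected [igraph::graph].
#' @param gene_set Character vector of gene names, a subset of the
#'   graph's vertices, with at least two members.
#' @param iterations Number of null draws (default 10000).
#' @param seed Optional RNG seed.
#' @return A one-row tibble: `observed`, `mean_null`, `sd_null`,
#'   `empirical_p`.
#' @export
network_clustering_test <- function(graph, gene_set, iterations = 10000L,
                                    seed = NULL) {
  if (length(gene_set) < 2L) abort("gene_set must have at least 2 genes")
  nodes <- igraph::V(graph)$name
  if (!all(gene_set %in% nodes)) {
    abort("gene_set must be a subset of the network's nodes")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  internal_edges <- function(set) {
    igraph::ecount(igraph::induced_subgraph(graph, set))
  }
  observed <- internal_edges(gene_set)
  k <- length(gene_set)
  null_counts <- vapply(seq_len(iterations), function(i) {
    internal_edges(sample(nodes, k))
  }, numeric(1))
  tibble(
    observed = observed,
    mean_null = mean(null_counts),
    sd_null = sd(null_counts),
    empirical_p = (1 + sum(null_counts >= observed)) / (iterations + 1)
  )
}
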