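#' Named signal-strength presets
#'
#' Each preset partitions the risk genes into strata that receive
#' P-values uniform on `(0, bound)`; the remaining risk genes (and all
#' non-risk genes) draw uniform `(0, 1)` P-values. The four presets vary
#' the fraction of risk genes carrying detectable signal, emulating
#' association studies of decreasing statistical power.
#'
#' @return A named list of signal configurations (see [signal_config()]).
#' @export
signal_presets <- function() {
  bounds <- c(1e-3, 5e-2, 0.3)
  fr <- function(f) signal_config(strata = tibble(fraction = rep(f, 3L),
                                                  bound = bounds))
  list(
    Strong = fr(0.25),
    Moderate = fr(0.20),
    Weak = fr(0.15),
    VeryWeak = fr(0.10)
  )
}

#' Build a signal-strength configuration
#'
#' @param strata A tibble with columns `fraction` (of risk genes) and
#'   `bound` (P-value upper bound for the stratum); fractions must sum to
#'   at most 1. Risk genes not covered by any stratum draw uniform (0, 1)
#'   P-values, exactly like non-risk genes.
#' @param name Optional label.
#' @return A list of class `signal_config`.
#' @export
signal_config <- function(strata, name = NULL) {
  strata <- as_tibble(strata)
  if (any(strata$fraction < 0 | strata$fraction > 1)) {
    abort("stratum fractions must lie in [0, 1]")
  }
  if (sum(strata$fraction) > 1 + 1e-9) {
    abort("stratum fractions must sum to at most 1")
  }
  if (any(strata$bound <= 0 | strata$bound > 1)) {
    abort("stratum bounds must lie in (0, 1]")
  }
  structure(list(strata = strata, name = name), class = "signal_config")
}

#' Simulate gene association P-values with planted risk-gene signal
#'
#' Non-risk genes draw P-values uniform on (0, 1). Risk genes are
#' partitioned at random into the configuration's strata (stratum k gets
#' `round(fraction_k * n_risk)` genes with P uniform on (0, bound_k));
#' leftover risk genes draw uniform (0, 1).
#'
#' @param genes Character vector of scoring genes.
#' @param risk_genes Character vector, subset of `genes`.
#' @param config A [signal_config()] or the name of a preset from
#'   [signal_presets()].
#' @param seed Optional RNG seed.
#' @return A tibble with columns `gene` and `pvalue`.
#' @export
simulate_signals <- function(genes, risk_genes, config = "Moderate",
                             seed = NULL) {
  if (!all(risk_genes %in% genes)) {
    abort("risk_genes must be a subset of genes")
  }
  if (is.character(config)) {
    presets <- signal_presets()
    if (!config %in% names(presets)) {
      abort(sprintf("unknown preset '%s'", config))
    }
    config <- presets[[config]]
  }
  if (!is.null(seed)) withr::local_seed(seed)
  p <- runif(length(genes))
  names(p) <- genes
  k <- length(risk_genes)
  if (k > 0L && nrow(config$strata) > 0L) {
    sizes <- round_half_up(config$strata$fraction * k)
    shuffled <- sample(risk_genes)
    offset <- 0L
    for (s in seq_along(sizes)) {
      sizes[s] <- min(sizes[s], k - offset)
      if (sizes[s] <= 0L) next
      members <- shuffled[(offset + 1L):(offset + sizes[s])]
      p[members] <- runif(sizes[s], 0, config$strata$bound[s])
      offset <- offset + sizes[s]
    }
  }
  tibble(gene = genes, pvalue = unname(p[genes]))
}

#' Generate a gene network with excess risk-gene connectivity
#'
#' Background pairs are connected independently with probability `p_out`
#' (an Erdos-Renyi graph); pairs of risk genes are instead connected with
#' probability `p_in`. With `p_in > p_out` the risk genes form a planted
#' module sharing excess connections, the network signature the scoring
#' model exploits.
#'
#' @param genes Character vector of genes (network nodes).
#' @param risk_genes Character vector, subset of `genes`.
#' @param p_in Edge probability within the risk set.
#' @param p_out Background edge probability.
#' @param seed Optional RNG seed.
#' @return An undirected unit-weight [igraph::graph] over `genes`.
#' @export
generate_network <- function(genes, risk_genes, p_in = 0.2, p_out = 0.01,
                             seed = NULL) {
  if (!all(risk_genes %in% genes)) {
    abort("risk_genes must be a subset of genes")
  }
  if (p_out > p_in || p_in > 1 || p_out < 0) {
    abort("need 0 <= p_out <= p_in <= 1")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  m <- length(genes)
  g <- igraph::sample_gnp(m, p_out, directed = FALSE)
  igraph::V(g)$name <- genes
  risk_idx <- match(risk_genes, genes)
  if (length(risk_idx) >= 2L) {
    pairs <- utils::combn(risk_idx, 2L)
    # replace the background draw within the risk set by the p_in draw
    old <- igraph::get_edge_ids(g, as.vector(pairs))
    g <- igraph::delete_edges(g, old[old > 0])
    keep <- runif(ncol(pairs)) < p_in
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    }
  }
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  g
}

#' Generate phenotype annotations with a shared risk-gene term pool
#'
#' Every gene draws background annotations at a gene-specific activity
#' rate (log-normal around `noise` with log-scale spread `activity_sd`),
#' reproducing the strong per-gene annotation-count heterogeneity of real
#' phenotype-ontology data: the first principal component of the
#' incidence matrix then tracks annotation counts, as it does in real
#' annotation sets. Risk genes concentrate part of their annotation
#' budget on a shared term pool: each risk gene targets
#' `Binomial(pool_size, p_pool)` pool terms and sheds the same number of
#' off-pool annotations, so per-gene counts are exactly preserved and
#' the count axis carries no risk signal — the planted structure lives
#' on later principal components.
#'
#' @param genes Character vector of genes.
#' @param risk_genes Character vector, subset of `genes`.
#' @param n_terms Total number of phenotype terms.
#' @param pool_size Number of shared-pool terms.
#' @param p_pool Per-pool-term annotation probability for risk genes.
#' @param noise Mean background annotation rate per gene-term pair.
#' @param activity_sd Log-scale standard deviation of per-gene activity;
#'   0 gives homogeneous genes.
#' @param seed Optional RNG seed.
#' @return A binary gene-by-term incidence matrix.
#' @export
generate_phenotypes <- function(genes, risk_genes, n_terms = 300L,
                                pool_size = 24L, p_pool = 0.6,
                                noise = 0.06, activity_sd = 0.5,
                                seed = NULL) {
  if (!all(risk_genes %in% genes)) {
    abort("risk_genes must be a subset of genes")
  }
  if (pool_size > n_terms) abort("pool_size cannot exceed n_terms")
  if (!is.null(seed)) withr::local_seed(seed)
  m <- length(genes)
  # mean-noise log-normal per-gene activity, capped at 0.9
  activity <- pmin(0.9, noise * exp(stats::rnorm(m, 0, activity_sd) -
                                      activity_sd^2 / 2))
  inc <- matrix(rbinom(m * n_terms, 1L, rep(activity, n_terms)), m, n_terms,
                dimnames = list(genes, paste0("T", seq_len(n_terms))))
  risk_idx <- match(risk_genes, genes)
  if (length(risk_idx) > 0L && pool_size > 0L) {
    pool <- seq_len(pool_size)
    off <- setdiff(seq_len(n_terms), pool)
    for (i in risk_idx) {
      total <- sum(inc[i, ])
      k <- min(rbinom(1L, pool_size, p_pool), total)
      row <- integer(n_terms)
      if (k > 0L) row[sample(pool, k)] <- 1L
      rest <- total - k
      if (rest > 0L) row[sample(off, min(rest, length(off)))] <- 1L
      inc[i, ] <- row
    }
  }
  inc
}

#' Simulate a complete synthetic study
#'
#' Generates a gene universe with a planted risk-gene subset, association
#' P-values under a signal-strength configuration, a network with excess
#' risk-gene connectivity, and phenotype annotations with a shared
#' risk-gene term pool. The world is fully determined by its parameters
#' and seed.
#'
#' @param m Number of scoring genes.
#' @param risk_fraction Fraction of genes planted as risk genes.
#' @param config Signal preset name or [signal_config()].
#' @param p_in,p_out Network edge probabilities (see [generate_network()]).
#' @param n_terms,pool_size,p_pool,noise,activity_sd Phenotype generator
#'   parameters (see [generate_phenotypes()]).
#' @param seed RNG seed.
#' @return A list of class `synthetic_world`: `genes`, `risk_genes`,
#'   `pvalues` (tibble), `network` (igraph), `phenotypes` (incidence
#'   matrix), `manifest` (parameter list).
#' @export
simulate_world <- function(m = 3000L, risk_fraction = 0.02,
                           config = "Moderate", p_in = 0.2, p_out = 0.01,
                           n_terms = 300L, pool_size = 24L, p_pool = 0.6,
                           noise = 0.06, activity_sd = 0.5, seed = 1L) {
  withr::local_seed(seed)
  genes <- sprintf("G%05d", seq_len(m))
  k <- round_half_up(m * risk_fraction)
  risk_genes <- sort(sample(genes, k))
  pvalues <- simulate_signals(genes, risk_genes, config)
  network <- generate_network(genes, risk_genes, p_in, p_out)
  phenotypes <- generate_phenotypes(genes, risk_genes, n_terms, pool_size,
                                    p_pool, noise, activity_sd)
  structure(
    list(
      genes = genes, risk_genes = risk_genes, pvalues = pvalues,
      network = network, phenotypes = phenotypes,
      manifest = list(m = m, risk_fraction = risk_fraction,
                      config = if (is.character(config)) config else "custom",
                      p_in = p_in, p_out = p_out, n_terms = n_terms,
                      pool_size = pool_size, p_pool = p_pool,
                      noise = noise, activity_sd = activity_sd,
                      seed = seed)
    ),
    class = "synthetic_world"
  )
}

#' Write a synthetic world to standard TSV files
#'
#' Emits `pvalues.tsv`, `network.tsv`, `phenotypes.tsv`, `risk_genes.tsv`
#' and `manifest.json` into a directory, in the formats the readers of
#' this package consume, so any world can be regenerated or reloaded
#' bit-exactly.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(world$pvalues, file.path(dir, "pvalues.tsv"),
                   progress = FALSE)
  el <- igraph::as_data_frame(world$network, what = "edges")
  edges <- tibble(gene1 = el$from, gene2 = el$to,
                  weight = el$weight %||% rep(1, nrow(el)))
  readr::write_tsv(edges, file.path(dir, "network.tsv"), progress = FALSE)
  idx <- which(world$phenotypes == 1L, arr.ind = TRUE)
  ann <- tibble(gene = rownames(world$phenotypes)[idx[, 1L]],
                term = colnames(world$phenotypes)[idx[, 2L]]) |>
    arrange(.data$gene, .data$term)
  readr::write_tsv(ann, file.path(dir, "phenotypes.tsv"), progress = FALSE)
  readr::write_tsv(tibble(gene = world$risk_genes),
                   file.path(dir, "risk_genes.tsv"), progress = FALSE)
  jsonlite::write_json(world$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
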