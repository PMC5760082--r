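#' Sampler parameter set
#'
#' Bundles and validates the tunable parameters of the risk-gene sampler.
#' Defaults are the optimized setting: 2% assumed risk genes, scaling
#' coefficient in `[0.1, 2]`, phenotype scoring on principal components 2
#' and 3, burn-in of 1000 iterations, rates recorded every 1000
#' iterations, and convergence once the mean absolute change of the
#' per-gene sampling rates between consecutive records drops below 0.001.
#'
#' @param x Assumed percentage of scoring genes that are risk genes.
#' @param a Lower-bound indicator value for non-risk genes, in (0, 1).
#' @param b Weight of the network-phenotype product (>= 0).
#' @param selected_components 1-based principal-component indices used in
#'   phenotype scoring.
#' @param burn_in Iterations discarded before rate accumulation.
#' @param record_every Iterations between convergence checks.
#' @param tol Convergence threshold on the mean absolute rate change.
#' @param max_iterations Safety cap on total iterations.
#' @param min_n Minimum number of sampled risk genes.
#' @param mode `"full"`, `"network-only"`, or `"phenotype-only"`.
#' @param net_mode `"transition"` (degree-normalized) or `"adjacency"`.
#' @param normalization `"fn"` (rank against sampled risk genes, the
#'   default), `"minmax"`, or `"raw"` (no normalization; diagnostic only).
#' @param seed Optional RNG seed recorded in the result.
#' @return A list of class `sampler_params`.
#' @export
sampler_params <- function(x = 2, a = 0.1, b = 1,
                           selected_components = c(2L, 3L),
                           burn_in = 1000L, record_every = 1000L,
                           tol = 0.001, max_iterations = 200000L,
                           min_n = 30L,
                           mode = c("full", "network-only", "phenotype-only"),
                           net_mode = c("transition", "adjacency"),
                           normalization = c("fn", "minmax", "raw"),
                           seed = NULL) {
  if (a <= 0 || a >= 1) abort("a must lie in (0, 1)")
  if (b < 0) abort("b must be nonnegative")
  if (x <= 0 || x >= 100) abort("x must lie in (0, 100)")
  if (burn_in < 1L || record_every < 1L) {
    abort("burn_in and record_every must be >= 1")
  }
  if (tol <= 0) abort("tol must be positive")
  structure(
    list(
      x = x, a = a, b = b,
      selected_components = as.integer(selected_components),
      burn_in = as.integer(burn_in),
      record_every = as.integer(record_every),
      tol = tol, max_iterations = as.integer(max_iterations),
      min_n = as.integer(min_n),
      mode = match.arg(mode), net_mode = match.arg(net_mode),
      normalization = match.arg(normalization), seed = seed
    ),
    class = "sampler_params"
  )
}

#' Weighted sampling of a risk assignment without replacement
#'
#' Draws `n` genes from the universe by sequential weighted sampling
#' without replacement: each draw picks gene g with probability
#' proportional to its weight among the remaining genes, then removes it.
#' Zero-weight genes are never drawn.
#'
#' @param weights Nonnegative sampling weights (the integrated scores).
#' @param n Number of genes to draw.
#' @return Integer vector of the drawn gene indices (unordered set).
#' @export
sample_assignment <- function(weights, n) {
  if (any(weights < 0)) abort("weights must be nonnegative")
  if (sum(weights > 0) < n) {
    abort("fewer positive weights than genes to sample")
  }
  sample.int(length(weights), size = n, replace = FALSE, prob = weights)
}

#' Run the risk-gene MCMC sampler
#'
#' Iterates the sampling chain over candidate risk-gene combinations:
#' starting from a uniform random assignment of `n` risk genes, each
#' iteration (1) computes raw network and phenotype scores against the
#' current assignment, normalizes them, and forms integrated scores, then
#' (2) draws the next assignment by weighted sampling without replacement
#' with the integrated scores as weights. Membership indicators are
#' accumulated after the burn-in; the per-gene sampling rate (cumulative
#' mean) is the final score, approximating the gene's risk probability.
#'
#' @param assoc Nonnegative association-score vector over the gene
#'   universe, or a tibble with columns `gene` and `assoc_score` (plus
#'   optionally `pvalue`).
#' @param network_model A `network_model` (or `NULL` in
#'   `"phenotype-only"` mode).
#' @param phenotype_model A `phenotype_model` (or `NULL` in
#'   `"network-only"` mode).
#' @param params A [sampler_params()] list.
#' @return An object of class `rvp_fit`; see [prioritize_genes()].
#' @export
run_sampler <- function(assoc, network_model = NULL, phenotype_model = NULL,
                        params = sampler_params()) {
  genes <- NULL
  pvals <- NULL
  if (is.data.frame(assoc)) {
    genes <- assoc$gene
    pvals <- assoc$pvalue
    assoc <- assoc$assoc_score
  }
  m <- length(assoc)
  if (any(assoc < 0) || anyNA(assoc)) {
    abort("association scores must be nonnegative and non-missing")
  }
  use_net <- params$mode != "phenotype-only"
  use_phe <- params$mode != "network-only"
  if (use_net) {
    if (is.null(network_model)) abort("network model required in this mode")
    if (nrow(network_model$adjacency) != m) {
      abort("network model does not match the gene universe")
    }
  }
  if (use_phe) {
    if (is.null(phenotype_model)) abort("phenotype model required in this mode")
    if (length(phenotype_model$genes) != m) {
      abort("phenotype model does not match the gene universe")
    }
    if (max(params$selected_components) > ncol(phenotype_model$eigenfeatures)) {
      abort("selected components exceed the phenotype model's eigenfeatures")
    }
    phenotype_model$selected_components <- params$selected_components
  }
  n <- risk_set_size(m, params$x, params$min_n)
  if (sum(assoc > 0) < n) {
    abort("fewer genes with positive association scores than risk genes to sample")
  }
  if (!is.null(params$seed)) withr::local_seed(params$seed)

  normalize <- switch(params$normalization,
    fn = function(raw, risk_idx) normalize_fn(raw, risk_idx),
    minmax = function(raw, risk_idx) normalize_minmax(raw),
    raw = function(raw, risk_idx) raw
  )

  risk_idx <- sample.int(m, n)
  v <- numeric(m)
  v[risk_idx] <- 1

  counts <- numeric(m)
  net_sum <- numeric(m)
  phe_sum <- numeric(m)
  post_iters <- 0L
  it <- 0L
  prev_rate <- NULL
  records <- list()
  converged <- FALSE

  while (it < params$max_iterations) {
    it <- it + 1L
    s_net <- if (use_net) {
      normalize(network_raw_scores(network_model, v, params$net_mode),
                risk_idx)
    } else rep(1, m)
    s_phe <- if (use_phe) {
      normalize(phenotype_raw_scores(phenotype_model, v), risk_idx)
    } else rep(1, m)
    w <- integrate_fast(assoc, s_net, s_phe, v == 1, params$a, params$b)

    if (it > params$burn_in) {
      counts <- counts + v
      net_sum <- net_sum + s_net
      phe_sum <- phe_sum + s_phe
      post_iters <- post_iters + 1L
      if (post_iters %% params$record_every == 0L) {
        rate <- counts / post_iters
        records[[length(records) + 1L]] <- rate
        if (!is.null(prev_rate) &&
            mean(abs(rate - prev_rate)) < params$tol) {
          converged <- TRUE
          break
        }
        prev_rate <- rate
      }
    }

    risk_idx <- sample_assignment(w, n)
    v <- numeric(m)
    v[risk_idx] <- 1
  }

  if (post_iters == 0L) {
    abort("sampler stopped before any post-burn-in iteration; increase max_iterations")
  }
  final <- counts / post_iters
  scores <- tibble(
    gene = genes %||% paste0("g", seq_len(m)),
    pvalue = pvals %||% rep(NA_real_, m),
    assoc_score = assoc,
    final_score = final,
    avg_net = if (use_net) net_sum / post_iters else rep(NA_real_, m),
    avg_phe = if (use_phe) phe_sum / post_iters else rep(NA_real_, m)
  )
  structure(
    list(
      scores = scores,
      n = n, m = m,
      params = params,
      n_iterations = it,
      post_burnin_iterations = post_iters,
      converged = converged,
      record_history = do.call(rbind, records),
      seed = params$seed
    ),
    class = "rvp_fit"
  )
}

#' Prioritize risk genes by integrated scoring
#'
#' High-level entry point: aligns gene-level P-values, a gene network and
#' phenotype annotations to a common scoring-gene universe, builds the
#' network and phenotype models, and runs the MCMC sampler. Genes lacking
#' network or phenotype data (as required by the chosen mode) are dropped
#' with a message. `mode = "burden-only"` skips the sampler and ranks by
#' association score alone.
#'
#' @param pvalues Tibble with columns `gene` and `pvalue` (see
#'   [read_gene_pvalues()]).
#' @param network An undirected [igraph::graph] or a prebuilt
#'   `network_model`; may be `NULL` for phenotype-only/burden-only modes.
#' @param phenotypes A binary gene-by-term incidence matrix (gene
#'   rownames) or a prebuilt `phenotype_model`; may be `NULL` for
#'   network-only/burden-only modes.
#' @param mode `"full"`, `"network-only"`, `"phenotype-only"`, or
#'   `"burden-only"`.
#' @param params A [sampler_params()] list; its `mode` is overridden by
#'   the `mode` argument.
#' @param quiet Suppress the dropped-gene message.
#' @return An object of class `rvp_fit` with elements `scores` (tibble:
#'   `gene`, `pvalue`, `assoc_score`, `final_score`, `avg_net`,
#'   `avg_phe`), `n`, `m`, `params`, `n_iterations`, `converged`,
#'   `record_history`, `seed`.
#' @export
prioritize_genes <- function(pvalues, network = NULL, phenotypes = NULL,
                             mode = c("full", "network-only",
                                      "phenotype-only", "burden-only"),
                             params = sampler_params(), quiet = FALSE) {
  mode <- match.arg(mode)
  pvalues <- as_tibble(pvalues)
  universe <- pvalues$gene
  use_net <- mode %in% c("full", "network-only")
  use_phe <- mode %in% c("full", "phenotype-only")
  if (use_net && is.null(network)) abort("network input required")
  if (use_phe && is.null(phenotypes)) abort("phenotype input required")
  if (use_net && !inherits(network, "network_model")) {
    universe <- intersect(universe, igraph::V(network)$name)
  }
  if (use_phe && !inherits(phenotypes, "phenotype_model")) {
    universe <- intersect(universe, rownames(phenotypes))
  }
  dropped <- setdiff(pvalues$gene, universe)
  if (length(dropped) > 0L && !quiet) {
    message(sprintf("dropping %d gene(s) without %s data",
                    length(dropped),
                    paste(c("network"[use_net], "phenotype"[use_phe]),
                          collapse = "/")))
  }
  if (length(universe) == 0L) abort("no genes shared across all inputs")
  assoc <- association_scores(pvalues, universe = universe)

  if (mode == "burden-only") {
    scores <- assoc |>
      mutate(final_score = .data$assoc_score,
             avg_net = NA_real_, avg_phe = NA_real_)
    return(structure(
      list(scores = scores, n = NA_integer_, m = nrow(scores),
           params = params, n_iterations = 0L,
           post_burnin_iterations = 0L, converged = TRUE,
           record_history = NULL, seed = params$seed),
      class = "rvp_fit"
    ))
  }
  params$mode <- mode
  net_model <- if (!use_net) NULL
    else if (inherits(network, "network_model")) network
    else build_network_model(network, universe)
  phe_model <- if (!use_phe) NULL
    else if (inherits(phenotypes, "phenotype_model")) phenotypes
    else build_phenotype_model(
      phenotypes, universe,
      selected_components = params$selected_components
    )
  run_sampler(assoc, net_model, phe_model, params)
}

#' Write run metadata of a fit as JSON
#'
#' Records the parameters, universe size, sampled risk-set size, iteration
#' count, convergence flag and seed of a fitted prioritization so a run can
#' be reproduced exactly.
#'
#' @param fit An `rvp_fit`.
#' @param path Output JSON path.
#' @return The metadata list, invisibly.
#' @export
write_run_metadata <- function(fit, path) {
  meta <- list(
    params = unclass(fit$params[setdiff(names(fit$params), "seed")]),
    seed = fit$seed,
    m = fit$m, n = fit$n,
    n_iterations = fit$n_iterations,
    post_burnin_iterations = fit$post_burnin_iterations,
    converged = fit$converged,
    n_records = if (is.null(fit$record_history)) 0L else
      nrow(fit$record_history)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(meta)
}
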