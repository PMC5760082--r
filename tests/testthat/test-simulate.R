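test_that("signal simulation allocates strata and keeps the null uniform", {
  genes <- sprintf("g%05d", 1:10000)
  risk <- genes[1:147]
  cfg <- signal_config(tibble::tibble(fraction = 0.25, bound = 0.001))
  sim <- simulate_signals(genes, risk, cfg, seed = 31)
  p_risk <- sim$pvalue[sim$gene %in% risk]
  # round(0.25 * 147) = 37 risk genes in the stratum; the leftover 110
  # draw uniform(0,1) and essentially never land below 1e-3
  expect_equal(sum(p_risk < 0.001), 37)
  # non-risk genes are uniform: mean 0.5 within Monte-Carlo error
  p_null <- sim$pvalue[!sim$gene %in% risk]
  expect_lt(abs(mean(p_null) - 0.5), 0.01)
  expect_gt(suppressWarnings(stats::ks.test(p_null, "punif"))$p.value, 0.01)
})

test_that("a degenerate single-stratum config leaves risk genes null", {
  genes <- paste0("g", 1:500)
  risk <- genes[1:20]
  cfg <- signal_config(tibble::tibble(fraction = 1, bound = 1))
  sim <- simulate_signals(genes, risk, cfg, seed = 32)
  expect_gt(suppressWarnings(
    stats::ks.test(sim$pvalue[sim$gene %in% risk], "punif"))$p.value, 0.05)
  expect_error(signal_config(tibble::tibble(fraction = c(0.7, 0.6),
                                            bound = c(0.1, 0.1))),
               "sum")
})

test_that("planted networks have the prescribed edge structure", {
  genes <- paste0("g", 1:200)
  risk <- genes[1:20]
  clique <- generate_network(genes, risk, p_in = 1, p_out = 0, seed = 33)
  sub <- igraph::induced_subgraph(clique, risk)
  expect_equal(igraph::ecount(sub), choose(20, 2))
  expect_equal(igraph::ecount(clique), choose(20, 2))

  withr::local_seed(34)
  p_in <- 0.3
  counts <- replicate(20, {
    g <- generate_network(genes, risk, p_in = p_in, p_out = 0.02)
    igraph::ecount(igraph::induced_subgraph(g, risk))
  })
  expected <- p_in * choose(20, 2)
  sd_bin <- sqrt(choose(20, 2) * p_in * (1 - p_in))
  expect_lt(abs(mean(counts) - expected), 3 * sd_bin / sqrt(20))

  g1 <- generate_network(genes, risk, 0.3, 0.02, seed = 35)
  g2 <- generate_network(genes, risk, 0.3, 0.02, seed = 35)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_error(generate_network(genes, risk, p_in = 0.1, p_out = 0.5),
               "p_out")
})

test_that("planted phenotype structure separates risk genes off the count axis", {
  genes <- paste0("g", 1:400)
  risk <- genes[1:20]
  inc <- generate_phenotypes(genes, risk, n_terms = 200, pool_size = 30,
                             p_pool = 1, noise = 0.08, activity_sd = 0.5,
                             seed = 36)
  # per-gene counts are preserved by the pool rewiring
  expect_lt(abs(mean(rowSums(inc[risk, ])) -
                  mean(rowSums(inc[!rownames(inc) %in% risk, ]))), 3)
  model <- build_phenotype_model(inc, genes)
  v <- as.numeric(genes %in% risk)
  mu <- phenotype_raw_scores(model, v)
  auc <- mean(outer(mu[v == 1], mu[v == 0], ">") +
                0.5 * outer(mu[v == 1], mu[v == 0], "=="))
  expect_gt(auc, 0.98)

  i1 <- generate_phenotypes(genes, risk, seed = 37)
  i2 <- generate_phenotypes(genes, risk, seed = 37)
  expect_identical(i1, i2)
})

test_that("phenotypes without a planted risk set carry no group structure", {
  genes <- paste0("g", 1:300)
  inc <- generate_phenotypes(genes, character(0), seed = 38)
  model <- build_phenotype_model(inc, genes)
  withr::local_seed(39)
  v <- numeric(300)
  v[sample(300, 15)] <- 1
  mu <- phenotype_raw_scores(model, v)
  # fitted probabilities cannot separate arbitrary labels: AUC near 0.5
  auc <- mean(outer(mu[v == 1], mu[v == 0], ">") +
                0.5 * outer(mu[v == 1], mu[v == 0], "=="))
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("top-k evaluation counts risk genes under dense tie-broken ranking", {
  scores <- tibble::tibble(
    gene = paste0("g", 1:10),
    final_score = c(9, 8, 7, 6, 5, 4, 3, 2, 1, 0) / 10
  )
  risk <- c("g1", "g3", "g9")
  expect_equal(evaluate_top_k(scores, risk, k = 5), 2L)
  expect_equal(evaluate_top_k(scores, risk, k = 10), 3L)
  expect_equal(evaluate_top_k(scores, character(0), k = 5), 0L)
  # all risk genes on top
  top <- tibble::tibble(gene = paste0("g", 1:10),
                        final_score = c(rep(1, 3), rep(0, 7)))
  expect_equal(evaluate_top_k(top, paste0("g", 1:3), k = 5), 3L)
  expect_error(evaluate_top_k(scores, risk, k = 11), "exceeds")
})

test_that("worlds are regenerable from their manifest", {
  w1 <- simulate_world(m = 120, seed = 41)
  w2 <- do.call(simulate_world, w1$manifest)
  expect_identical(w1$pvalues, w2$pvalues)
  expect_identical(w1$phenotypes, w2$phenotypes)
  expect_identical(igraph::as_edgelist(w1$network),
                   igraph::as_edgelist(w2$network))

  dir <- withr::local_tempdir()
  write_world(w1, dir)
  expect_true(all(file.exists(file.path(
    dir, c("pvalues.tsv", "network.tsv", "phenotypes.tsv",
           "risk_genes.tsv", "manifest.json")))))
  back <- read_gene_pvalues(file.path(dir, "pvalues.tsv"))
  expect_equal(back$pvalue, w1$pvalues$pvalue)
})

test_that("negative control separates planted signal from permuted signal", {
  world <- small_world(m = 400, seed = 43, config = "Strong")
  params <- fast_params(seed = 44, x = 5)
  nc1 <- negative_control(world$pvalues, world$network, world$phenotypes,
                          params = params, n_trials = 3, k = 20, seed = 45)
  nc2 <- negative_control(world$pvalues, world$network, world$phenotypes,
                          params = params, n_trials = 3, k = 20, seed = 45)
  expect_identical(nc1, nc2)
  fit <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                          params = params, quiet = TRUE)
  # planted signal concentrates the sampler: the observed top-20 scores
  # exceed the permuted-signal top-20 by more than 2 null SDs on average
  observed_top <- sort(fit$scores$final_score, decreasing = TRUE)[1:20]
  expect_gt(mean(observed_top - nc1$mean_score[1:20]),
            2 * mean(nc1$sd_score[1:20]))
})
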