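test_that("weighted sampling without replacement honors the weights", {
  expect_equal(sample_assignment(c(1, 0, 0, 0), 1), 1L)
  withr::local_seed(8)
  # zero-weight genes are never drawn
  draws <- replicate(500, sample_assignment(c(1, 0, 2, 3), 2))
  expect_false(any(draws == 2))
  expect_error(sample_assignment(c(1, 0, 0), 2), "positive weights")
  expect_error(sample_assignment(c(-1, 1, 1), 1), "nonnegative")
})

test_that("uniform weights give symmetric inclusion frequencies", {
  withr::local_seed(9)
  counts <- integer(4)
  n_draws <- 100000L
  for (i in seq_len(n_draws)) {
    idx <- sample_assignment(rep(1, 4), 2)
    counts[idx] <- counts[idx] + 1L
  }
  expect_true(all(abs(counts / n_draws - 0.5) < 0.01))
})

test_that("the sampler is bit-reproducible under a fixed seed", {
  world <- small_world(m = 120, seed = 21)
  params <- fast_params(seed = 33)
  f1 <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                         params = params, quiet = TRUE)
  f2 <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                         params = params, quiet = TRUE)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$record_history, f2$record_history)
})

test_that("final scores are sampling rates: in [0, 1] and summing to n", {
  world <- small_world(m = 150, seed = 22)
  fit <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                          params = fast_params(seed = 5), quiet = TRUE)
  expect_true(all(fit$scores$final_score >= 0 &
                    fit$scores$final_score <= 1))
  expect_equal(sum(fit$scores$final_score), fit$n, tolerance = 1e-9)
  expect_true(all(fit$scores$avg_net >= 0 & fit$scores$avg_net <= 1))
  expect_true(all(fit$scores$avg_phe >= 0 & fit$scores$avg_phe <= 1))
})

test_that("a deterministic chain converges at the second record", {
  # only one gene can ever be sampled, so consecutive records are equal
  model <- toy_network_model(data.frame(from = "A", to = "B"),
                             genes = c("A", "B"))
  assoc <- tibble::tibble(gene = c("A", "B"), pvalue = c(0.01, 1),
                          assoc_score = c(2, 0))
  params <- sampler_params(x = 50, min_n = 1L, burn_in = 5L,
                           record_every = 5L, mode = "network-only",
                           seed = 1)
  fit <- run_sampler(assoc, network_model = model, params = params)
  expect_true(fit$converged)
  expect_equal(nrow(fit$record_history), 2L)
  expect_equal(fit$scores$final_score, c(1, 0))
})

test_that("with b = 0 the chain depends only on association scores and a", {
  world <- small_world(m = 100, seed = 23)
  alt_network <- generate_network(world$genes, character(0), p_in = 0.5,
                                  p_out = 0.05, seed = 99)
  params <- fast_params(seed = 11, b = 1e-12)
  f1 <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                         params = params, quiet = TRUE)
  f2 <- prioritize_genes(world$pvalues, alt_network, world$phenotypes,
                         params = params, quiet = TRUE)
  expect_equal(f1$scores$final_score, f2$scores$final_score,
               tolerance = 1e-9)
})

test_that("sampler errors are informative", {
  assoc <- tibble::tibble(gene = c("A", "B"), pvalue = c(1, 1),
                          assoc_score = c(0, 0))
  model <- toy_network_model(data.frame(from = "A", to = "B"),
                             genes = c("A", "B"))
  params <- sampler_params(x = 50, min_n = 1L, mode = "network-only")
  expect_error(run_sampler(assoc, network_model = model, params = params),
               "positive association")
})

test_that("empirical rates match exact stationary marginals (network toy)", {
  model <- toy_network_model(
    data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E")),
    genes = c("A", "B", "C", "D", "E", "F")
  )
  assoc_vals <- c(1.2, 0.4, 2.0, 0.7, 0.05, 1.0)
  exact <- oracle_stationary_marginals(assoc_vals, net_model = model,
                                       n = 2L)
  assoc <- tibble::tibble(gene = model$genes, pvalue = 10^-assoc_vals,
                          assoc_score = assoc_vals)
  params <- sampler_params(x = 100 * 2 / 6, min_n = 1L, burn_in = 1000L,
                           record_every = 50000L, tol = 1e-9,
                           max_iterations = 51000L, mode = "network-only",
                           seed = 17)
  fit <- run_sampler(assoc, network_model = model, params = params)
  expect_lt(max(abs(fit$scores$final_score - exact)), 0.02)
  expect_equal(sum(exact), 2, tolerance = 1e-8)
})

test_that("raising one gene's association score never lowers its marginal", {
  model <- toy_network_model(
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")),
    genes = c("A", "B", "C", "D", "E")
  )
  base <- c(0.5, 1.0, 0.3, 0.8, 0.6)
  for (target in c(1L, 3L, 5L)) {
    prev <- -Inf
    for (boost in c(0, 0.5, 1.5)) {
      assoc <- base
      assoc[target] <- base[target] + boost
      marg <- oracle_stationary_marginals(assoc, net_model = model, n = 2L)
      expect_gte(marg[target], prev - 1e-10)
      prev <- marg[target]
    }
  }
})

test_that("burden-only mode ranks by association score alone", {
  world <- small_world(m = 80, seed = 24)
  fit <- prioritize_genes(world$pvalues, mode = "burden-only", quiet = TRUE)
  expect_equal(fit$scores$final_score, fit$scores$assoc_score)
  tab <- score_table(fit)
  expect_equal(tab$gene[1],
               world$pvalues$gene[which.min(world$pvalues$pvalue)])
})

test_that("tidy, glance and plots expose the fit", {
  world <- small_world(m = 100, seed = 25)
  fit <- prioritize_genes(world$pvalues, world$network, world$phenotypes,
                          params = fast_params(seed = 2), quiet = TRUE)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 100L)
  expect_equal(td$rank, seq_len(100L))
  gl <- generics::glance(fit)
  expect_equal(gl$m, 100L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_convergence(fit), "ggplot")
  meta_path <- withr::local_tempfile(fileext = ".json")
  meta <- write_run_metadata(fit, meta_path)
  expect_true(file.exists(meta_path))
  expect_equal(jsonlite::read_json(meta_path)$n, fit$n)
})
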