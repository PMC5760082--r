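test_that("cohort AAF matches direct allele counting", {
  g <- matrix(c(1, 1, 1, rep(0, 181)), ncol = 1)  # 3 het among 184
  expect_equal(compute_cohort_aaf(g), 3 / 368, tolerance = 1e-12)

  expect_equal(compute_cohort_aaf(matrix(0, 5, 1)), 0)
  expect_equal(compute_cohort_aaf(matrix(c(2, 0), 2, 1)), 0.5)

  # missing calls shrink the denominator
  gm <- matrix(c(1, NA, 0, 0), 4, 1)
  expect_equal(compute_cohort_aaf(gm), 1 / 6)
  expect_error(compute_cohort_aaf(matrix(NA_integer_, 3, 1)),
               "no non-missing")
})

test_that("variant filtering applies all four thresholds", {
  variants <- tibble::tibble(
    gene = paste0("G", 1:5),
    cohort_aaf = c(0.005, 0.02, 0.005, 0.005, 0.005),
    reference_aaf = c(0.0005, 0.0005, NA, 0.0005, 0.0005),
    cadd_scaled = c(25, 30, 19.9, 25, 25),
    missing_rate = c(0, 0, 0, 0.2, 0.05)
  )
  kept <- filter_variants(variants)
  expect_equal(kept$gene, c("G1", "G5"))
  # idempotent and order-independent
  expect_equal(filter_variants(kept), kept)
  shuffled <- variants[c(3, 1, 5, 2, 4), ]
  expect_equal(sort(filter_variants(shuffled)$gene), sort(kept$gene))
  # missing reference AAF passes that criterion
  na_ref <- filter_variants(tibble::tibble(
    gene = "G6", cohort_aaf = 0.004, reference_aaf = NA_real_,
    cadd_scaled = 21, missing_rate = 0))
  expect_equal(nrow(na_ref), 1L)
})

test_that("burden score test reproduces the hand-derived statistic", {
  # one variant, 2 het carriers among 90 cases, 0 among 94 controls
  g <- matrix(0, 184, 1)
  g[1:2, 1] <- 1
  status <- c(rep("case", 90), rep("control", 94))
  res <- burden_test(g, status, weights = "unweighted")
  # frozen from the score-test arithmetic: mu = 90/184, U = 2(1 - mu),
  # Var = mu(1-mu) * sum((B_i - mean(B))^2)
  mu <- 90 / 184
  expect_equal(res$score_u, 2 * (1 - mu), tolerance = 1e-10)
  expect_equal(res$var_u, 0.494331, tolerance = 1e-5)
  expect_equal(res$statistic, 2.11184, tolerance = 1e-4)
  expect_equal(res$pvalue, 0.146163, tolerance = 1e-4)
})

test_that("balanced carriers give a null-ish P and degenerate burdens give P = 1", {
  g <- matrix(0, 180, 1)
  g[c(1, 2, 91, 92), 1] <- 1  # 2 case + 2 control carriers, 90/90
  status <- rep(c("case", "control"), each = 90)
  res <- burden_test(g, status, weights = "unweighted")
  expect_gt(res$pvalue, 0.99)

  # identical burden for everyone -> zero variance -> P = 1
  res2 <- burden_test(matrix(1, 20, 1), rep(c(1, 0), 10),
                      weights = "unweighted")
  expect_equal(res2$pvalue, 1)

  expect_error(burden_test(g, rep("case", 180)), "cases and controls")
})

test_that("beta MAF weights upweight the rarest variants", {
  g <- cbind(c(1, rep(0, 99)), rbinom(100, 1, 0.3))
  w_rare <- dbeta(compute_cohort_aaf(g)[1], 1, 25)
  w_common <- dbeta(min(compute_cohort_aaf(g)[2],
                        1 - compute_cohort_aaf(g)[2]), 1, 25)
  expect_gt(w_rare, w_common)
})

test_that("association scores are -log10 P with flooring", {
  tab <- tibble::tibble(gene = c("A", "B", "C", "D"),
                        pvalue = c(1, 0.5, 1e-6, 1e-310))
  scores <- association_scores(tab)
  expect_equal(scores$assoc_score[1], 0)
  expect_equal(scores$assoc_score[2], 0.30103, tolerance = 1e-5)
  expect_equal(scores$assoc_score[3], 6)
  expect_equal(scores$assoc_score[4], 300)  # floored at 1e-300
  # monotone decreasing in P
  expect_true(all(diff(scores$assoc_score) >= 0))
  expect_error(association_scores(tab, universe = c("A", "Z")), "Z")
})

test_that("permutation nulls are seeded and approximately calibrated", {
  withr::local_seed(7)
  n_ind <- 200L
  dosages <- do.call(cbind, replicate(30, null_gene_dosages(n_ind, 4), simplify = FALSE))
  variants <- tibble::tibble(
    gene = rep(paste0("G", 1:30), each = 4L),
    chrom = "1"
  )
  samples <- tibble::tibble(
    sample_id = paste0("S", seq_len(n_ind)),
    status = rep(c("case", "control"), each = n_ind / 2),
    sex = "unknown"
  )
  a <- permute_status_null(dosages, variants, samples, n_sets = 3, seed = 11)
  b <- permute_status_null(dosages, variants, samples, n_sets = 3, seed = 11)
  expect_identical(a, b)
  expect_error(permute_status_null(dosages, variants, samples, n_sets = 0),
               ">= 1")
  # under the null the P-values should not pile up near 0
  expect_lt(mean(a$pvalue < 0.05), 0.15)
})
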