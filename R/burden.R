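#' Cohort alternative allele frequency per variant
#'
#' Computes the in-cohort alternative allele frequency of each variant from
#' the dosage matrix: the sum of alternative alleles over non-missing calls
#' divided by twice the number of non-missing diploid calls.
#'
#' @param dosages Individuals-by-variants integer matrix with entries in
#'   `{0, 1, 2}`; `NA` marks a missing genotype.
#' @return A numeric vector of AAFs, one per variant (column).
#' @examples
#' g <- matrix(c(1, 1, 1, rep(0, 181)), ncol = 1) # 3 het among 184 samples
#' compute_cohort_aaf(g) # 3/368
#' @export
compute_cohort_aaf <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (length(dosages) == 0L) abort("empty genotype matrix")
  called <- base::colSums(!is.na(dosages))
  if (any(called == 0L)) {
    abort(sprintf("variant(s) with no non-missing genotype calls: %s",
                  paste(which(called == 0L), collapse = ", ")))
  }
  base::colSums(dosages, na.rm = TRUE) / (2 * called)
}

#' Filter variants on frequency, deleteriousness and missingness
#'
#' Keeps rare, predicted-deleterious variants: cohort AAF below `aaf_max`,
#' reference-population AAF below `aaf_max` (a missing reference AAF
#' passes), CADD scaled score at least `cadd_min`, and missing-genotype
#' rate at most `missing_max`. The filter is idempotent and
#' order-independent.
#'
#' @param variants A variant tibble with columns `cohort_aaf`,
#'   `reference_aaf`, `cadd_scaled` and optionally `missing_rate`.
#' @param aaf_max Maximum (exclusive) allele frequency, default 0.01.
#' @param cadd_min Minimum (inclusive) CADD scaled score, default 20.
#' @param missing_max Maximum (inclusive) missing-genotype rate, default 0.10.
#' @return The kept subset of `variants`, same columns.
#' @export
filter_variants <- function(variants, aaf_max = 0.01, cadd_min = 20,
                            missing_max = 0.10) {
  miss <- variants$missing_rate %||% rep(0, nrow(variants))
  miss[is.na(miss)] <- 0
  keep <- variants$cohort_aaf < aaf_max &
    (is.na(variants$reference_aaf) | variants$reference_aaf < aaf_max) &
    variants$cadd_scaled >= cadd_min &
    miss <= missing_max
  variants[keep & !is.na(keep), , drop = FALSE]
}

#' Kernel-regression style burden test for one gene
#'
#' Score test for association between case/control status and the weighted
#' rare-allele burden of a gene. Under the null logistic model
#' (intercept plus optional covariates) the score statistic
#' `U^2 / Var(U)` for the burden `B_i = sum_j w_j g_ij` is referred to a
#' 1-df chi-square distribution. Default weights are the Beta(1, 25)
#' density evaluated at each variant's cohort minor allele frequency;
#' `weights = "unweighted"` uses unit weights.
#'
#' @param gene_dosages Individuals-by-variants dosage matrix for the
#'   variants of one gene (`NA` imputed to 0).
#' @param status Numeric/logical vector: 1/TRUE for cases, 0/FALSE for
#'   controls; or a character vector of `"case"`/`"control"`.
#' @param covariates Optional numeric matrix or data frame of per-individual
#'   covariates included in the null model.
#' @param weights `"beta"` (default) or `"unweighted"`.
#' @param maf Optional per-variant minor allele frequencies for the Beta
#'   weights; computed from `gene_dosages` when omitted.
#' @return A one-row tibble with `pvalue`, `statistic`, `score_u`,
#'   `var_u`, `n_variants`.
#' @export
burden_test <- function(gene_dosages, status, covariates = NULL,
                        weights = c("beta", "unweighted"), maf = NULL) {
  weights <- match.arg(weights)
  g <- as.matrix(gene_dosages)
  g[is.na(g)] <- 0
  y <- normalize_status(status)
  if (length(y) != nrow(g)) abort("status length must match genotype rows")
  if (all(y == 1) || all(y == 0)) {
    abort("burden test requires both cases and controls")
  }
  if (ncol(g) < 1L) abort("burden test requires at least one variant")
  w <- if (weights == "beta") {
    if (is.null(maf)) {
      aaf <- base::colSums(g) / (2 * nrow(g))
      maf <- pmin(aaf, 1 - aaf)
    }
    dbeta(maf, 1, 25)
  } else {
    rep(1, ncol(g))
  }
  burden <- as.numeric(g %*% w)
  score_test_1df(burden, y, covariates)
}

# Score test of a single linear burden term added to a null logistic model.
# Var(U) uses the efficient information, projecting out the fitted
# nuisance parameters (intercept + covariates).
score_test_1df <- function(burden, y, covariates = NULL) {
  n <- length(y)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    X <- cbind(X, as.matrix(as.data.frame(covariates)))
  }
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  wt <- mu * (1 - mu)
  U <- sum(burden * (y - mu))
  XtWX <- crossprod(X, X * wt)
  XtWB <- crossprod(X, burden * wt)
  proj <- tryCatch(solve(XtWX, XtWB), error = function(e) NULL)
  var_u <- if (is.null(proj)) 0 else
    sum(burden^2 * wt) - as.numeric(crossprod(XtWB, proj))
  if (!is.finite(var_u) || var_u <= 1e-12) {
    return(tibble(pvalue = 1, statistic = 0, score_u = U, var_u = 0,
                  n_variants = NA_integer_))
  }
  stat <- U^2 / var_u
  tibble(pvalue = pchisq(stat, df = 1, lower.tail = FALSE),
         statistic = stat, score_u = U, var_u = var_u,
         n_variants = NA_integer_)
}

#' Gene-level burden tests over a variant set
#'
#' Groups (already filtered) variants by gene and runs [burden_test()] per
#' gene. The sex covariate is applied only to genes with variants on
#' chromosome X by default, or to every gene with `sex_covariate = "always"`.
#'
#' @param dosages Individuals-by-variants dosage matrix; column order must
#'   match the rows of `variants`.
#' @param variants Variant tibble with at least `gene` and `chrom`.
#' @param samples Sample sheet tibble (`sample_id`, `status`, `sex`) with
#'   rows matching the rows of `dosages`.
#' @param weights Passed to [burden_test()].
#' @param sex_covariate `"chrx"` (default) or `"always"`.
#' @return A tibble with one row per gene: `gene`, `pvalue`, `assoc_score`,
#'   `n_variants`, `case_alleles`, `control_alleles`.
#' @export
burden_test_genes <- function(dosages, variants, samples,
                              weights = c("beta", "unweighted"),
                              sex_covariate = c("chrx", "always")) {
  weights <- match.arg(weights)
  sex_covariate <- match.arg(sex_covariate)
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(variants)) {
    abort("dosage columns must match variant rows")
  }
  y <- normalize_status(samples$status)
  sex_num <- as.numeric(factor(samples$sex, levels = c("female", "male",
                                                       "unknown")))
  genes <- unique(variants$gene)
  purrr::map_dfr(genes, function(gn) {
    idx <- which(variants$gene == gn)
    g <- dosages[, idx, drop = FALSE]
    g[is.na(g)] <- 0
    on_x <- any(grepl("^(chr)?x$", variants$chrom[idx], ignore.case = TRUE))
    cov <- if (sex_covariate == "always" || on_x) {
      cbind(sex = sex_num)
    } else NULL
    res <- burden_test(g, y, covariates = cov, weights = weights)
    tibble(
      gene = gn,
      pvalue = res$pvalue,
      assoc_score = -log10(res$pvalue),
      n_variants = length(idx),
      case_alleles = sum(g[y == 1, , drop = FALSE]),
      control_alleles = sum(g[y == 0, , drop = FALSE])
    )
  })
}

#' Convert gene P-values to association scores
#'
#' The genotype-based score of a gene is minus log10 of its burden-test
#' P-value, floored at `p_floor` to keep scores finite.
#'
#' @param pvalues A tibble with columns `gene` and `pvalue` (or a named
#'   numeric vector of P-values).
#' @param universe Optional character vector of scoring genes; every gene
#'   in the universe must have a P-value.
#' @param p_floor Smallest P-value used in the conversion.
#' @return A tibble with columns `gene`, `pvalue`, `assoc_score`.
#' @export
association_scores <- function(pvalues, universe = NULL, p_floor = 1e-300) {
  if (is.numeric(pvalues) && !is.null(names(pvalues))) {
    pvalues <- tibble(gene = names(pvalues), pvalue = unname(pvalues))
  }
  tab <- as_tibble(pvalues)
  if (!is.null(universe)) {
    missing_genes <- setdiff(universe, tab$gene)
    if (length(missing_genes) > 0L) {
      abort(sprintf("missing P-value for gene(s): %s",
                    paste(missing_genes, collapse = ", ")))
    }
    tab <- tab[match(universe, tab$gene), , drop = FALSE]
  }
  if (anyNA(tab$pvalue)) abort("NA P-value in association input")
  mutate(tab, assoc_score = -log10(pmax(.data$pvalue, p_floor)))
}

#' Null association signals by permuting case/control labels
#'
#' Generates sets of null gene-level P-values by uniformly permuting the
#' case/control status labels and rerunning the gene-level burden tests.
#' Covariates (e.g. sex) stay attached to their individuals.
#'
#' @inheritParams burden_test_genes
#' @param n_sets Number of permutation sets.
#' @param seed RNG seed; the same seed reproduces the same sets.
#' @return A tibble with columns `set`, `gene`, `pvalue`, `assoc_score`.
#' @export
permute_status_null <- function(dosages, variants, samples, n_sets,
                                seed = NULL,
                                weights = c("beta", "unweighted")) {
  if (!is_scalar_number(n_sets) || n_sets < 1) abort("n_sets must be >= 1")
  weights <- match.arg(weights)
  if (!is.null(seed)) withr::local_seed(seed)
  purrr::map_dfr(seq_len(n_sets), function(k) {
    perm <- samples
    perm$status <- sample(samples$status)
    res <- burden_test_genes(dosages, variants, perm, weights = weights)
    mutate(res, set = k, .before = 1L) |>
      select("set", "gene", "pvalue", "assoc_score")
  })
}

# status in any of several encodings -> 0/1 numeric
normalize_status <- function(status) {
  if (is.character(status) || is.factor(status)) {
    s <- tolower(as.character(status))
    if (!all(s %in% c("case", "control"))) {
      abort("status must be 'case'/'control' or 0/1")
    }
    as.numeric(s == "case")
  } else {
    s <- as.numeric(status)
    if (!all(s %in% c(0, 1))) abort("status must be 'case'/'control' or 0/1")
    s
  }
}
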