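#' Principal-component eigenfeatures of a phenotype incidence matrix
#'
#' Computes per-gene coordinates on the principal components of the
#' column-centered (not scaled) binary gene-by-term incidence matrix.
#' Components are ordered by decreasing explained variance. The first
#' component mainly tracks each gene's annotation count and is excluded
#' from the default scoring selection downstream.
#'
#' @param incidence Binary gene-by-term matrix (genes in rows).
#' @param n_components Number of leading components to keep.
#' @return A genes-by-components numeric matrix of coordinates (zero
#'   column means). A constant incidence matrix yields all-zero
#'   coordinates.
#' @export
phenotype_eigenfeatures <- function(incidence, n_components = 10L) {
  X <- as.matrix(incidence)
  if (nrow(X) < 2L || ncol(X) < 2L) abort("need at least 2 genes and 2 terms")
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  centered <- scale(X, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-12)) {
    out <- matrix(0, nrow(X), n_components)
    rownames(out) <- rownames(X)
    colnames(out) <- paste0("PC", seq_len(n_components))
    return(out)
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  scores <- pc$x
  if (ncol(scores) < n_components) {
    pad <- matrix(0, nrow(X), n_components - ncol(scores))
    scores <- cbind(scores, pad)
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Build a phenotype model over a gene universe
#'
#' Aligns the phenotype incidence matrix to the ordered scoring-gene
#' universe and precomputes the principal-component eigenfeatures used by
#' phenotype scoring. Genes without phenotype annotations get all-zero
#' incidence rows.
#'
#' @param incidence Binary gene-by-term matrix with gene rownames.
#' @param genes Character vector: the ordered scoring-gene universe.
#' @param n_components Number of leading components to retain.
#' @param selected_components 1-based component indices used in the
#'   logistic scoring fit; the default `c(2, 3)` excludes the
#'   annotation-count component.
#' @return An object of class `phenotype_model` with elements `incidence`,
#'   `eigenfeatures`, `selected_components`, `genes`.
#' @export
build_phenotype_model <- function(incidence, genes, n_components = 10L,
                                  selected_components = c(2L, 3L)) {
  inc <- matrix(0L, length(genes), ncol(incidence),
                dimnames = list(genes, colnames(incidence)))
  shared <- intersect(genes, rownames(incidence))
  inc[shared, ] <- as.matrix(incidence)[shared, , drop = FALSE]
  n_components <- max(n_components, max(selected_components))
  ef <- phenotype_eigenfeatures(inc, n_components)
  if (max(selected_components) > ncol(ef)) {
    abort("selected components exceed available eigenfeatures")
  }
  structure(
    list(
      incidence = inc,
      eigenfeatures = ef,
      selected_components = as.integer(selected_components),
      genes = genes
    ),
    class = "phenotype_model"
  )
}

#' Raw phenotype scores given a risk assignment
#'
#' Regresses the binary risk-gene indicator on the selected eigenfeature
#' coordinates by logistic regression and returns the fitted probability
#' for every gene. A small ridge penalty on the slopes (lambda = 1e-6)
#' keeps the fit defined under complete separation.
#'
#' @param model A `phenotype_model` from [build_phenotype_model()].
#' @param v Binary 0/1 vector over the model's gene universe.
#' @param lambda Ridge penalty on slope coefficients.
#' @return Numeric vector of fitted probabilities (the raw phenotype
#'   scores), one per gene.
#' @export
phenotype_raw_scores <- function(model, v, lambda = 1e-6) {
  if (length(v) != length(model$genes)) {
    abort("risk vector length must match gene universe")
  }
  if (all(v == 0) || all(v == 1)) {
    abort("risk assignment must contain both risk and non-risk genes")
  }
  X <- model$eigenfeatures[, model$selected_components, drop = FALSE]
  fit <- ridge_logistic(X, v, lambda = lambda)
  as.numeric(plogis(fit$intercept + X %*% fit$slopes))
}

# Newton-Raphson logistic regression with a ridge penalty on the slopes
# only (intercept unpenalized). Deterministic; converges to ~1e-12.
ridge_logistic <- function(X, y, lambda = 1e-6, max_iter = 50L,
                           tol = 1e-10) {
  Z <- cbind(1, as.matrix(X))
  p <- ncol(Z)
  pen_vec <- c(0, rep(lambda, p - 1L))
  beta <- numeric(p)
  beta[1L] <- stats::qlogis(mean(y))
  for (it in seq_len(max_iter)) {
    eta <- Z %*% beta
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    w[w < 1e-12] <- 1e-12
    grad <- crossprod(Z, y - mu) - pen_vec * beta
    hess <- crossprod(Z, Z * as.numeric(w))
    diag(hess) <- diag(hess) + pen_vec
    step <- tryCatch(solve(hess, grad), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  list(intercept = beta[1L], slopes = beta[-1L])
}
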