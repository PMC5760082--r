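#' Build a network model over a gene universe
#'
#' Aligns an undirected weighted gene graph to the ordered scoring-gene
#' universe, producing the adjacency matrix `A`, its column-normalized
#' transition matrix `N`, and per-gene weighted degrees. Genes absent from
#' the graph get zero rows/columns (and hence zero raw network scores).
#'
#' @param graph An undirected [igraph::graph] with optional `weight` edge
#'   attribute (default 1).
#' @param genes Character vector: the ordered scoring-gene universe.
#' @return An object of class `network_model` with elements `adjacency`,
#'   `transition` (sparse matrices over `genes`), `degree`, and `genes`.
#' @export
build_network_model <- function(graph, genes) {
  if (igraph::is_directed(graph)) abort("network must be undirected")
  present <- intersect(genes, igraph::V(graph)$name)
  sub <- igraph::induced_subgraph(graph, present)
  A <- Matrix::Matrix(0, length(genes), length(genes), sparse = TRUE,
                      dimnames = list(genes, genes))
  if (length(present) > 0L && igraph::ecount(sub) > 0L) {
    attr_name <- if ("weight" %in% igraph::edge_attr_names(sub)) "weight" else NULL
    Asub <- igraph::as_adjacency_matrix(sub, attr = attr_name, sparse = TRUE)
    idx <- match(rownames(Asub), genes)
    A[idx, idx] <- Asub
  }
  structure(
    list(
      adjacency = A,
      transition = build_transition_matrix(A),
      degree = setNames(as.numeric(Matrix::colSums(A)), genes),
      genes = genes
    ),
    class = "network_model"
  )
}

#' Column-normalized transition matrix of a gene network
#'
#' Divides each column of the symmetric adjacency matrix by its column sum
#' (the gene's weighted degree); zero-degree columns stay all-zero.
#'
#' @param adjacency Symmetric nonnegative (sparse or dense) matrix.
#' @return A sparse transition matrix of the same dimension.
#' @export
build_transition_matrix <- function(adjacency) {
  A <- methods::as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix")
  if (any(A@x < 0)) abort("adjacency weights must be nonnegative")
  if (!Matrix::isSymmetric(A, tol = 1e-10)) {
    abort("adjacency matrix must be symmetric")
  }
  cs <- Matrix::colSums(A)
  inv <- ifelse(cs > 0, 1 / cs, 0)
  A %*% Matrix::Diagonal(x = inv)
}

#' Raw network scores of all genes given a risk assignment
#'
#' The raw network score of gene g is its connectivity propensity to the
#' currently sampled risk genes: `(N v)_g` with the column-normalized
#' transition matrix (degree-aware, the default) or `(A v)_g` with the
#' plain adjacency matrix (risk-neighbor count/weight).
#'
#' @param model A `network_model` from [build_network_model()].
#' @param v Binary 0/1 vector over the model's gene universe.
#' @param mode `"transition"` (default) or `"adjacency"`.
#' @return Numeric vector of raw network scores over the universe.
#' @export
network_raw_scores <- function(model, v, mode = c("transition", "adjacency")) {
  mode <- match.arg(mode)
  M <- if (mode == "transition") model$transition else model$adjacency
  if (length(v) != nrow(M)) abort("risk vector length must match gene universe")
  as.numeric(M %*% v)
}
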