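#' Read gene-level association P-values
#'
#' Reads a two-column tab-separated file of gene symbols and burden-test
#' P-values. Lines starting with `#` are ignored; a header row is detected
#' automatically.
#'
#' @param path Path to a TSV file with columns `gene` and `pvalue`.
#' @return A tibble with columns `gene` (character) and `pvalue` (double),
#'   one row per gene.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tpvalue", "G1\t0.119", "G2\t0.028"), tf)
#' read_gene_pvalues(tf)
#' @export
read_gene_pvalues <- function(path) {
  tab <- read_tsv_auto(path, c("gene", "pvalue"), numeric_cols = 2L)
  pv <- suppressWarnings(as.numeric(tab[[2L]]))
  if (anyNA(pv)) {
    abort(sprintf("non-numeric P-value for gene(s): %s",
                  paste(tab[[1L]][is.na(pv)], collapse = ", ")))
  }
  if (any(pv <= 0 | pv > 1)) {
    bad <- tab[[1L]][pv <= 0 | pv > 1]
    abort(sprintf("P out of range (0,1] for gene(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dup <- unique(tab[[1L]][duplicated(tab[[1L]])])
  if (length(dup) > 0L) {
    abort(sprintf("duplicate gene(s): %s", paste(dup, collapse = ", ")))
  }
  tibble(gene = as.character(tab[[1L]]), pvalue = pv)
}

#' Read an undirected gene network from an edge list
#'
#' Reads a tab-separated edge list with columns `gene1`, `gene2` and an
#' optional `weight` (default 1). Self-loops are dropped and duplicate
#' undirected edges are collapsed, keeping the maximum weight.
#'
#' @param path Path to the edge-list TSV.
#' @return An undirected [igraph::graph] with a `weight` edge attribute.
#' @export
read_network <- function(path) {
  tab <- read_tsv_auto(path, c("gene1", "gene2", "weight"), numeric_cols = 3L,
                       min_cols = 2L)
  w <- if (ncol(tab) >= 3L) suppressWarnings(as.numeric(tab[[3L]])) else
    rep(1, nrow(tab))
  w[is.na(w)] <- 1
  if (any(w < 0)) abort("negative edge weight in network file")
  edges <- tibble(
    gene1 = as.character(tab[[1L]]),
    gene2 = as.character(tab[[2L]]),
    weight = w
  )
  edges_from_table(edges)
}

# Build the canonical undirected weighted graph from an edge tibble.
edges_from_table <- function(edges) {
  nodes <- unique(c(edges$gene1, edges$gene2))
  edges <- dplyr::filter(edges, .data$gene1 != .data$gene2)
  if (nrow(edges) > 0L) {
    key <- ifelse(edges$gene1 < edges$gene2,
                  paste(edges$gene1, edges$gene2, sep = "\r"),
                  paste(edges$gene2, edges$gene1, sep = "\r"))
    edges <- edges |>
      mutate(key = key) |>
      group_by(.data$key) |>
      summarise(gene1 = .data$gene1[1L], gene2 = .data$gene2[1L],
                weight = max(.data$weight), .groups = "drop") |>
      select("gene1", "gene2", "weight")
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Read gene-phenotype annotations into a binary incidence matrix
#'
#' Reads long-format (gene, term) annotation rows and, if a parent map is
#' supplied, closes each annotation over all transitive ancestor terms
#' (the "is a" paths of a phenotype ontology).
#'
#' @param path Path to a TSV with columns `gene` and `term`.
#' @param parent_path Optional path to a TSV with columns `term` and
#'   `parent` describing the ontology hierarchy.
#' @return A binary gene-by-term incidence matrix (base matrix with
#'   dimnames), rows are genes, columns are terms.
#' @export
read_phenotype_annotations <- function(path, parent_path = NULL) {
  tab <- read_tsv_auto(path, c("gene", "term"), numeric_cols = integer(0))
  ann <- distinct(tibble(gene = as.character(tab[[1L]]),
                         term = as.character(tab[[2L]])))
  parent_map <- NULL
  if (!is.null(parent_path)) {
    pm <- read_tsv_auto(parent_path, c("term", "parent"),
                        numeric_cols = integer(0))
    parent_map <- distinct(tibble(term = as.character(pm[[1L]]),
                                  parent = as.character(pm[[2L]])))
  }
  build_incidence(ann, parent_map)
}

# Long annotations (+ optional parent map) -> binary incidence matrix,
# with ancestor closure when a parent map is given.
build_incidence <- function(ann, parent_map = NULL) {
  if (!is.null(parent_map) && nrow(parent_map) > 0L) {
    anc <- ancestor_sets(parent_map)
    extra <- ann |>
      dplyr::filter(.data$term %in% names(anc)) |>
      mutate(term = unname(anc[.data$term])) |>
      tidyr::unnest_longer("term")
    ann <- distinct(bind_rows(ann, extra))
  }
  genes <- sort(unique(ann$gene))
  terms <- sort(unique(ann$term))
  inc <- matrix(0L, length(genes), length(terms),
                dimnames = list(genes, terms))
  inc[cbind(match(ann$gene, genes), match(ann$term, terms))] <- 1L
  inc
}

# term -> character vector of all transitive ancestors; errors on cycles.
ancestor_sets <- function(parent_map) {
  g <- igraph::graph_from_data_frame(parent_map, directed = TRUE)
  if (!igraph::is_dag(g)) abort("cycle in phenotype parent map")
  terms <- intersect(unique(parent_map$term), igraph::V(g)$name)
  out <- lapply(terms, function(tm) {
    anc <- igraph::subcomponent(g, tm, mode = "out")$name
    setdiff(anc, tm)
  })
  names(out) <- terms
  out[lengths(out) > 0L]
}

#' Read a case/control sample sheet
#'
#' @param path Path to a TSV with columns `sample_id`, `status`
#'   (`case`/`control`) and `sex` (`male`/`female`/`unknown`).
#' @return A tibble with those three columns.
#' @export
read_sample_sheet <- function(path) {
  tab <- read_tsv_auto(path, c("sample_id", "status", "sex"),
                       numeric_cols = integer(0), min_cols = 2L)
  sex <- if (ncol(tab) >= 3L) tolower(as.character(tab[[3L]])) else
    rep("unknown", nrow(tab))
  sheet <- tibble(
    sample_id = as.character(tab[[1L]]),
    status = tolower(as.character(tab[[2L]])),
    sex = sex
  )
  if (anyDuplicated(sheet$sample_id)) abort("duplicate sample ids")
  if (!all(sheet$status %in% c("case", "control"))) {
    abort("status must be 'case' or 'control'")
  }
  if (!all(sheet$sex %in% c("male", "female", "unknown"))) {
    abort("sex must be 'male', 'female' or 'unknown'")
  }
  if (!any(sheet$status == "case") || !any(sheet$status == "control")) {
    abort("need at least one case and one control")
  }
  sheet
}

#' Read a variant annotation table
#'
#' Reads a TSV mirroring the per-variant record: `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `cohort_aaf`, `reference_aaf`, `cadd_scaled`,
#' `functional_class`. Missing reference AAF may be encoded as `NA` or an
#' empty field.
#'
#' @param path Path to the variant TSV.
#' @return A tibble of variant records.
#' @export
read_variant_table <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("chrom", "pos", "ref", "alt", "gene", "cadd_scaled")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    abort(sprintf("variant table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  tab <- mutate(tab,
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    gene = as.character(.data$gene),
    cadd_scaled = as.numeric(.data$cadd_scaled)
  )
  for (col in c("cohort_aaf", "reference_aaf")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  if (!"functional_class" %in% names(tab)) {
    tab$functional_class <- NA_character_
  }
  bad_aaf <- stats::na.omit(c(tab$cohort_aaf, tab$reference_aaf))
  if (any(bad_aaf < 0 | bad_aaf > 1)) abort("AAF outside [0, 1]")
  if (any(tab$pos < 1L, na.rm = TRUE)) abort("variant pos must be >= 1")
  as_tibble(tab)
}

#' Read genotypes and variant annotations from a VCF file
#'
#' Parses a VCF with `vcfR`, extracting per-individual dosages from the GT
#' field and per-variant annotation from configurable INFO keys. The cohort
#' alternative allele frequency is always recomputed from the genotypes
#' themselves; the INFO key only supplies the reference-population AAF.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param gene_key,cadd_key,ref_aaf_key INFO keys holding the gene symbol,
#'   CADD scaled score, and reference-population AAF.
#' @return A list with `variants` (tibble of variant records, including the
#'   recomputed `cohort_aaf` and per-variant `missing_rate`) and `dosages`
#'   (individuals-by-variants integer matrix, `NA` for missing calls).
#' @export
read_vcf_genotypes <- function(path, gene_key = "GENE", cadd_key = "CADD",
                               ref_aaf_key = "REF_AF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required to read VCF input")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  info_field <- function(key) {
    vcfR::extract.info(vcf, element = key)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  dos <- apply(gt, 2, function(col) {
    alleles <- strsplit(gsub("\\|", "/", col), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) == 0L || any(a == ".") || all(is.na(a))) return(NA_integer_)
      sum(a != "0")
    }, integer(1))
  })
  # vcfR returns variants x samples; we keep individuals x variants
  dos <- base::t(dos)
  colnames(dos) <- paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":")
  variants <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    gene = as.character(info_field(gene_key)),
    reference_aaf = suppressWarnings(as.numeric(info_field(ref_aaf_key))),
    cadd_scaled = suppressWarnings(as.numeric(info_field(cadd_key))),
    functional_class = NA_character_
  )
  variants$cohort_aaf <- compute_cohort_aaf(dos)
  variants$missing_rate <- colMeans(is.na(dos))
  list(variants = variants, dosages = dos)
}

#' Write ranked gene scores to a TSV file
#'
#' Writes the per-gene result table sorted by final score (descending,
#' ties broken alphabetically by gene symbol) with a dense 1-based rank.
#'
#' @param result A fitted prioritization object (see [prioritize_genes()])
#'   or a data frame with at least `gene` and `final_score` columns.
#' @param path Output TSV path.
#' @return The written tibble, invisibly.
#' @export
write_scores <- function(result, path) {
  tab <- score_table(result)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(tab)
}

#' Ranked score table of a prioritization result
#'
#' @param result A fitted prioritization object or a data frame with at
#'   least `gene` and `final_score` columns.
#' @return A tibble with columns `gene`, `final_score`, `rank`, `pvalue`,
#'   `assoc_score`, `avg_net`, `avg_phe`, sorted by decreasing final score.
#' @export
score_table <- function(result) {
  tab <- if (inherits(result, "rvp_fit")) result$scores else as_tibble(result)
  if (nrow(tab) == 0L) {
    return(tibble(gene = character(), final_score = double(),
                  rank = integer(), pvalue = double(),
                  assoc_score = double(), avg_net = double(),
                  avg_phe = double()))
  }
  for (col in c("pvalue", "assoc_score", "avg_net", "avg_phe")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  tab |>
    arrange(desc(.data$final_score), .data$gene) |>
    mutate(rank = row_number()) |>
    select("gene", "final_score", "rank", "pvalue", "assoc_score",
           "avg_net", "avg_phe")
}

# Shared TSV reader: '#' comments, tabs, automatic header detection.
# A first row is treated as a header when its fields match the expected
# column names, or when a column expected to be numeric fails to parse.
read_tsv_auto <- function(path, expected, numeric_cols, min_cols = length(expected)) {
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tab) == 0L) {
    out <- tibble::as_tibble(matrix(character(), 0, length(expected),
                                    dimnames = list(NULL, expected)))
    return(out)
  }
  if (ncol(tab) < min_cols) {
    abort(sprintf("expected at least %d tab-separated columns in %s",
                  min_cols, path))
  }
  first <- tolower(as.character(tab[1L, ]))
  known <- c("gene", "pvalue", "p", "p_value", "gene1", "gene2", "weight",
             "term", "parent", "sample_id", "status", "sex")
  header <- any(first %in% known)
  if (!header && length(numeric_cols) > 0L) {
    num_ok <- vapply(numeric_cols[numeric_cols <= ncol(tab)], function(j) {
      !is.na(suppressWarnings(as.numeric(first[j])))
    }, logical(1))
    header <- length(num_ok) > 0L && !all(num_ok)
  }
  if (header) tab <- tab[-1L, , drop = FALSE]
  tab
}
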