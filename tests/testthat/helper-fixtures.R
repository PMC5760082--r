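# Small fixture builders shared across test files.

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Tiny path graph A-B-C as an igraph with unit weights.
path_graph_abc <- function() {
  g <- igraph::make_graph(~ A - B, B - C)
  igraph::E(g)$weight <- c(1, 1)
  g
}

# A toy network model over explicit gene names.
toy_network_model <- function(edges, genes) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = genes)
  igraph::E(g)$weight <- rep(1, igraph::ecount(g))
  build_network_model(g, genes)
}

# A toy phenotype model with explicit eigenfeature coordinates: builds an
# incidence-free model object directly so tests can control coordinates.
toy_phenotype_model <- function(coords, genes,
                                selected = seq_len(ncol(coords))) {
  coords <- sweep(coords, 2, colMeans(coords))
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- genes
  structure(
    list(incidence = NULL, eigenfeatures = coords,
         selected_components = as.integer(selected), genes = genes),
    class = "phenotype_model"
  )
}

# Simulated rare-variant dosage matrix for one gene under the null
# (no case/control difference).
null_gene_dosages <- function(n_ind, n_var, carrier_p = 0.01) {
  matrix(rbinom(n_ind * n_var, 2L, carrier_p), n_ind, n_var)
}

# Minimal VCF text for the CLI/burden tests: 6 variants, 8 samples.
write_toy_vcf <- function() {
  samples <- paste0("S", 1:8)
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD scaled\">",
    "##INFO=<ID=REF_AF,Number=1,Type=Float,Description=\"Reference AAF\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt_row <- function(chrom, pos, ref, alt, gene, cadd, ref_af, gts) {
    info <- sprintf("GENE=%s;CADD=%s%s", gene, cadd,
                    if (is.na(ref_af)) "" else sprintf(";REF_AF=%s", ref_af))
    paste(c(chrom, pos, ".", ref, alt, "100", "PASS", info, "GT", gts),
          collapse = "\t")
  }
  body <- c(
    gt_row("1", 100, "A", "T", "GENE1", 25.0, 0.001,
           c("0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0")),
    gt_row("1", 200, "G", "C", "GENE1", 30.0, NA,
           c("0/0", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0")),
    gt_row("2", 300, "C", "A", "GENE2", 15.0, 0.001,   # fails CADD
           c("0/1", "0/0", "0/0", "0/0", "0/1", "0/0", "0/0", "0/0")),
    gt_row("2", 400, "T", "G", "GENE2", 28.0, 0.20,    # fails ref AAF
           c("0/0", "0/0", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0")),
    gt_row("3", 500, "A", "G", "GENE3", 22.0, 0.001,
           c("0/1", "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0")),
    gt_row("3", 600, "C", "T", "GENE4", 35.0, 0.001,   # common in cohort
           c("1/1", "1/1", "0/1", "0/1", "1/1", "0/1", "0/1", "1/1"))
  )
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(c(header, body), path)
  path
}

toy_sample_sheet <- function() {
  tibble::tibble(
    sample_id = paste0("S", 1:8),
    status = rep(c("case", "control"), each = 4L),
    sex = rep(c("male", "female"), 4L)
  )
}

# Small synthetic world for sampler-level tests.
small_world <- function(m = 300L, seed = 42L, ...) {
  simulate_world(m = m, risk_fraction = 0.05, seed = seed, ...)
}

# Fast sampler parameters for small worlds.
fast_params <- function(seed = 1L, ...) {
  sampler_params(min_n = 1L, burn_in = 200L, record_every = 200L,
                 max_iterations = 4000L, seed = seed, ...)
}
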