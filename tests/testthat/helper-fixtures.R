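# Small in-code fixtures shared across test files.

tiny_matrix <- function(vals, genes = NULL, samples = NULL) {
  n <- length(vals) %/% length(samples %||% vals[1])
  m <- matrix(vals, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv_matrix <- function(vals, genes, samples, path, id_col = "gene_id") {
  m <- matrix(vals, nrow = length(genes), dimnames = list(genes, samples))
  write_omics_matrix(m, path, id_col = id_col)
  path
}

# a complete small fixture directory built from the synthetic generator
small_fixture_dir <- function(seed = 5, n_genes = 60, n_samples = 40, ...) {
  cohort <- generate_cohort(n_genes = n_genes, n_samples = n_samples,
                            seed = seed, ...)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  files <- make_fixture_files(cohort, dir)
  list(cohort = cohort, dir = dir, files = files)
}

fixture_config <- function(files, ...) {
  utils::modifyList(default_run_config(),
                    c(list(expression = files$expression,
                           methylation_probes = files$methylation_probes,
                           probe_manifest = files$probe_manifest,
                           mirna = files$mirna,
                           mirna_targets = files$mirna_targets,
                           annotation = files$annotation,
                           labels = files$labels),
                      list(...)))
}

# random non-negative CP factors for planted-tensor tests
random_cp_factors <- function(n, m, k, rank, seed) {
  set.seed(seed)
  list(G = matrix(runif(n * rank, 0.1, 1), n, rank),
       P = matrix(runif(m * rank, 0.1, 1), m, rank),
       O = matrix(runif(k * rank, 0.1, 1), k, rank))
}
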