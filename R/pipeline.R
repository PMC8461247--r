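# End-to-end orchestration: raw files -> gene-centric matrices -> tensor ->
# decomposition -> label-specific features -> cross-validated scoring, with
# deterministic artifacts written per stage.

#' Default run configuration
#'
#' Flat named list of every pipeline setting; file-based configs
#' ([read_run_config()]) are merged over these defaults.
#'
#' @return Named list.
#' @export
default_run_config <- function() {
  list(
    expression = NULL, methylation_probes = NULL, probe_manifest = NULL,
    mirna = NULL, mirna_targets = NULL, annotation = NULL, labels = NULL,
    out_dir = NULL,
    rank = 120L, alpha = 0.01, seed = 1L, n_starts = 5L, max_iter = 500L,
    tol = 1e-7, n_folds = 10L, mode = "strict", omics_subset = "",
    input_kind = "gene_values", mirna_mode = "geometric",
    promoter_window = 2000L, max_missing_fraction = 0.8,
    min_class_fraction = 0.05, max_classes = 5L,
    hidden = 100L, epochs = 500L, cv_n_starts = 2L, cv_max_iter = 200L
  )
}

#' Read a flat key = value run configuration file
#'
#' One `key = value` per line; `#` starts a comment; values are parsed as
#' numbers where possible. Unknown keys are an error (catches typos before
#' any compute).
#'
#' @param path Config file path.
#' @return Full config list (defaults overridden by the file).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- default_run_config()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a run configuration as a flat key = value file
#'
#' @param config Config list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  keep <- !vapply(config, is.null, logical(1))
  writeLines(sprintf("%s = %s", names(config)[keep],
                     vapply(config[keep], as.character, character(1))), path)
  invisible(path)
}

#' Build raw gene-centric matrices from input files
#'
#' Reads the per-omics tables, aggregates methylation probes and miRNA
#' bundles per gene, intersects samples across layers, and applies the
#' protein-coding / methylation-missingness gene filter. Values are still on
#' their raw scale (normalization happens later, or inside the strict
#' evaluation protocol).
#'
#' @param config Run config with the input paths set.
#' @return List: `raw` (named list GE/ME/MI of gene x sample matrices with
#'   identical axes), `annotation`, `labels`, `samples`, `genes`.
#' @export
build_gene_centric <- function(config) {
  for (key in c("expression", "methylation_probes", "probe_manifest",
                "mirna", "mirna_targets", "annotation", "labels")) {
    if (is.null(config[[key]])) stop("config is missing input path: ", key)
    if (!file.exists(config[[key]])) stop("input file not found: ", config[[key]])
  }
  expr <- read_omics_matrix(config$expression, "expression")
  probes <- read_omics_matrix(config$methylation_probes, "methylation_probe")
  manifest <- read_probe_manifest(config$probe_manifest)
  mirna <- read_omics_matrix(config$mirna, "mirna")
  tmap <- read_mirna_targets(config$mirna_targets)
  ann <- read_gene_annotation(config$annotation)
  labels <- read_labels(config$labels)

  meth <- methylation_to_gene(probes, manifest, ann,
                              window = as.integer(config$promoter_window))
  mi <- mirna_to_gene(mirna, tmap, gene_ids = rownames(expr),
                      mode = config$mirna_mode)

  samples <- match_samples(list(GE = expr, ME = meth, MI = mi))
  raw <- list(GE = unclass(expr)[, samples, drop = FALSE],
              ME = unclass(meth)[, samples, drop = FALSE],
              MI = unclass(mi)[, samples, drop = FALSE])
  genes <- filter_genes(raw, ann, max_missing_fraction = config$max_missing_fraction)
  raw <- lapply(raw, function(m) m[genes, , drop = FALSE])

  missing_lab <- setdiff(samples, names(labels))
  if (length(missing_lab) > 0)
    stop("samples without labels: ", paste(utils::head(missing_lab, 5), collapse = ", "))
  list(raw = raw, annotation = ann, labels = labels[samples],
       samples = samples, genes = genes)
}

#' Normalize one raw gene-centric layer for the transductive tensor
#'
#' Impute per-gene means, `log2(x+1)` for expression-scale layers (skipped
#' for methylation betas), quantile-normalize across samples, min-max scale.
#'
#' @param m Raw gene x sample matrix.
#' @param log2_first Apply the log step.
#' @return Scaled matrix in `[0,1]`.
#' @export
normalize_layer <- function(m, log2_first = TRUE) {
  m <- impute_gene_mean(unclass(m))
  m <- if (log2_first) log2_quantile_normalize(m) else quantile_normalize(m)
  minmax_scale_slice(m)
}

#' Run the full pipeline and write its artifact directory
#'
#' Stages: read + gene-centric assembly, tensor construction, non-negative
#' CP decomposition, one-vs-rest L1 feature selection, gene and omics
#' assignment, and cross-validated scoring (strict split-first protocol by
#' default, transductive otherwise). Artifacts — tensor slices, factor
#' matrices, per-label weights, gene assignment, evaluation summary, the
#' verbatim config and a run log — are pure functions of (inputs, config,
#' seed).
#'
#' @param config Config list ([default_run_config()] keys) or a path to a
#'   `key = value` config file.
#' @return Invisibly, a list with the main in-memory results (`tensor`,
#'   `decomposition`, `selection`, `assignment`, `evaluation`, paths).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config[!vapply(config, is.null, logical(1))])
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    note("stage %s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  for (key in c("expression", "methylation_probes", "mirna", "annotation", "labels"))
    if (!is.null(cfg[[key]]))
      note("input %s: %s md5=%s", key, cfg[[key]], tools::md5sum(cfg[[key]])[[1]])
  note("seed=%d rank=%d alpha=%g mode=%s", as.integer(cfg$seed),
       as.integer(cfg$rank), cfg$alpha, cfg$mode)

  gc_data <- stage("gene_centric", build_gene_centric(cfg))
  raw <- gc_data$raw
  labels <- gc_data$labels

  tensor <- stage("tensor", {
    slices <- list(GE = normalize_layer(raw$GE, TRUE),
                   ME = normalize_layer(raw$ME, FALSE),
                   MI = normalize_layer(raw$MI, TRUE))
    assemble_tensor(lapply(names(slices), function(o)
      omics_matrix(slices[[o]], omics_name = o)) |> stats::setNames(names(slices)),
      scale = FALSE)
  })
  write_tensor(tensor, file.path(cfg$out_dir, "tensor"),
               meta = list(seed = as.integer(cfg$seed)))

  decomp <- stage("decompose",
    parafac_nn(tensor, rank = as.integer(cfg$rank), seed = as.integer(cfg$seed),
               max_iter = as.integer(cfg$max_iter), tol = cfg$tol,
               n_starts = as.integer(cfg$n_starts)))
  write_decomposition(decomp, file.path(cfg$out_dir, "decomposition"))
  note("decomposition relative error %.6g", decomp$relative_error)

  selection <- stage("select",
    select_all_labels(decomp$C_p, labels, alpha = cfg$alpha))
  assignment <- assign_genes(decomp$C_g, selection)
  omics_map <- assign_omics(decomp$C_o)
  write_selection(selection, assignment, omics_map,
                  file.path(cfg$out_dir, "selection"))

  subset <- if (nzchar(cfg$omics_subset)) strsplit(cfg$omics_subset, ",")[[1]] else NULL
  evcfg <- eval_config(n_folds = as.integer(cfg$n_folds), seed = as.integer(cfg$seed),
                       mode = cfg$mode, omics_subset = subset,
                       input_kind = cfg$input_kind, rank = as.integer(cfg$rank),
                       alpha = cfg$alpha, n_starts = as.integer(cfg$cv_n_starts),
                       max_iter = as.integer(cfg$cv_max_iter),
                       hidden = as.integer(cfg$hidden), epochs = as.integer(cfg$epochs))
  evaluation <- stage("classify", {
    if (cfg$mode == "strict") {
      cv_strict(raw, labels, evcfg)
    } else {
      genes <- sort(unique(unlist(assignment$label_genes)))
      X <- build_classifier_input(tensor, genes, subset, cfg$input_kind,
                                  C_p = decomp$C_p, features = selection$union)
      cross_validate(X, labels, evcfg)
    }
  })
  note("mean macro F1 = %.4f", evaluation$mean_f1)

  jsonlite::write_json(
    list(mode = evaluation$mode, fold_f1 = evaluation$fold_f1,
         mean_f1 = evaluation$mean_f1, macro_f1_pooled = evaluation$macro_f1_pooled,
         confusion = as.data.frame.matrix(unclass(evaluation$confusion))),
    file.path(cfg$out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.txt"))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))

  invisible(list(tensor = tensor, decomposition = decomp, selection = selection,
                 assignment = assignment, omics_map = omics_map,
                 evaluation = evaluation, out_dir = cfg$out_dir,
                 raw = raw, labels = labels))
}

#' Sweep the L1 penalty and score each setting
#'
#' Repeats feature selection and classification for each alpha on a fixed
#' decomposition (transductive scoring: the sweep compares selections, so
#' the decomposition is held constant). An alpha so large that no feature
#' survives yields `NA` F1 with a notice.
#'
#' @param decomp `cp_decomposition`.
#' @param tensor The decomposed `omics_tensor`.
#' @param labels Named label vector.
#' @param alphas Numeric vector of penalty weights.
#' @param config [eval_config()].
#' @return data.frame `alpha, n_features, n_genes, mean_f1`.
#' @export
run_alpha_sweep <- function(decomp, tensor, labels, alphas = c(0, 0.001, 0.005, 0.01, 0.05, 0.1),
                            config = eval_config(mode = "transductive")) {
  rows <- lapply(alphas, function(a) {
    sel <- select_all_labels(decomp$C_p, labels, alpha = a)
    if (length(sel$union) == 0) {
      message("alpha = ", a, ": no feature selected; classification skipped")
      return(data.frame(alpha = a, n_features = 0L, n_genes = 0L, mean_f1 = NA_real_))
    }
    asg <- assign_genes(decomp$C_g, sel)
    genes <- sort(unique(unlist(asg$label_genes)))
    if (length(genes) == 0) {
      message("alpha = ", a, ": no gene maps to a selected feature; skipped")
      return(data.frame(alpha = a, n_features = length(sel$union), n_genes = 0L,
                        mean_f1 = NA_real_))
    }
    X <- build_classifier_input(tensor, genes, config$omics_subset,
                                config$input_kind, C_p = decomp$C_p,
                                features = sel$union)
    res <- cross_validate(X, labels, config)
    data.frame(alpha = a, n_features = length(sel$union),
               n_genes = length(genes), mean_f1 = res$mean_f1)
  })
  do.call(rbind, rows)
}
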