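# Synthetic matched multi-omics cohorts with planted CP structure: the test
# bed for the whole pipeline. Every label owns a block of latent features;
# samples of a label load strongly on their features, gene factors are
# sparse, omics factors encode which layers carry each feature's signal.

#' Generate a synthetic multi-omics cohort with planted factors
#'
#' Builds non-negative factor matrices `G*` (genes x R, sparse support),
#' `P*` (samples x R, label-structured) and `O*` (omics x R, routing), forms
#' the tensor `sum_f g* (x) p* (x) o*`, adds Gaussian noise truncated at zero
#' and min-max scales each omics slice to `[0,1]`.
#'
#' Sample loadings: feature f owned by label l gives that label's samples
#' `signal + |N(0, 0.2*signal)|` and all others `|N(0, 0.05*signal)|`.
#' Gene factors: each feature is supported on a random 5% of genes with
#' Uniform(0.5, 1.5) weights. Omics routing presets: `"balanced"` (every
#' feature loads on all layers), `"GE"`/`"ME"`/`"MI"` (all signal in one
#' layer), `"split_GE_ME"` (features of the first half of the labels live
#' only in GE, the rest only in ME — single-layer classifiers then miss half
#' the label structure); a custom K x R non-negative matrix is also accepted.
#'
#' @param n_genes,n_samples,n_omics,rank_true Tensor dimensions and true rank.
#' @param n_labels Number of sample classes; `rank_true` must be >= this so
#'   every label owns at least one feature.
#' @param signal Mean loading of a label's samples on its own features.
#' @param noise_sd Standard deviation of the truncated Gaussian noise.
#' @param omics_routing Preset name or K x R matrix (see above).
#' @param gene_support Fraction of genes supporting each feature.
#' @param seed Integer seed; all outputs are reproducible from it.
#' @return List: `tensor` (`omics_tensor`), `labels` (named vector), `truth`
#'   (`synthetic_truth`: planted `G`, `P`, `O`, `label_features`, settings).
#' @export
generate_cohort <- function(n_genes = 300L, n_samples = 80L, n_omics = 3L,
                            rank_true = 8L, n_labels = 4L, signal = 1,
                            noise_sd = 0.05, omics_routing = "balanced",
                            gene_support = 0.05, seed = 1L) {
  if (rank_true < n_labels)
    stop("rank_true must be >= n_labels (each label needs its own planted feature)")
  set.seed(seed %% .Machine$integer.max)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  omics_names <- c("GE", "ME", "MI", paste0("O", seq_len(max(0, n_omics - 3))))[seq_len(n_omics)]
  label_names <- paste0("L", seq_len(n_labels))
  labels <- stats::setNames(rep_len(label_names, n_samples), sample_ids)

  # contiguous blocks of features per label
  owner <- rep_len(seq_len(n_labels), rank_true)
  owner <- sort(owner)
  label_features <- split(seq_len(rank_true), label_names[owner])

  # patient factor
  P <- matrix(abs(stats::rnorm(n_samples * rank_true, 0, 0.05 * signal)),
              n_samples, rank_true)
  for (f in seq_len(rank_true)) {
    own <- labels == label_names[owner[f]]
    P[own, f] <- signal + abs(stats::rnorm(sum(own), 0, 0.2 * signal))
  }

  # sparse gene factor
  n_sup <- max(1L, round(gene_support * n_genes))
  G <- matrix(0, n_genes, rank_true)
  for (f in seq_len(rank_true)) {
    sup <- sample.int(n_genes, n_sup)
    G[sup, f] <- stats::runif(n_sup, 0.5, 1.5)
  }

  O <- routing_matrix(omics_routing, n_omics, rank_true, owner, n_labels)

  dimnames(G) <- list(gene_ids, NULL)
  dimnames(P) <- list(sample_ids, NULL)
  dimnames(O) <- list(omics_names, NULL)

  clean <- reconstruct(G, P, O)
  noise <- array(stats::rnorm(length(clean), 0, noise_sd), dim = dim(clean))
  noisy <- pmax(clean + noise, 0)
  dimnames(noisy) <- list(gene_ids, sample_ids, omics_names)

  slices <- lapply(seq_len(n_omics), function(k) {
    m <- noisy[, , k]
    omics_matrix(minmax_scale_slice(m), omics_name = omics_names[k])
  })
  names(slices) <- omics_names
  tensor <- assemble_tensor(slices, scale = FALSE)  # already in [0,1]

  truth <- structure(list(G = G, P = P, O = O, labels = labels,
                          label_features = label_features,
                          owner = label_names[owner],
                          signal = signal, noise_sd = noise_sd,
                          omics_routing = omics_routing, seed = seed),
                     class = "synthetic_truth")
  list(tensor = tensor, labels = labels, truth = truth)
}

routing_matrix <- function(routing, K, R, owner, n_labels) {
  if (is.matrix(routing)) {
    stopifnot(nrow(routing) == K, ncol(routing) == R, all(routing >= 0))
    return(routing)
  }
  O <- matrix(0, K, R)
  base <- 0.02  # faint background loading keeps the tensor strictly trilinear
  switch(routing,
    balanced = {
      O[] <- stats::runif(K * R, 0.5, 1)
    },
    GE = { O[] <- base; O[1, ] <- 1 },
    ME = { O[] <- base; O[2, ] <- 1 },
    MI = { O[] <- base; O[3, ] <- 1 },
    split_GE_ME = {
      O[] <- base
      first_half <- owner <= ceiling(n_labels / 2)
      O[1, first_half] <- 1   # GE carries the first half of the labels
      O[2, !first_half] <- 1  # ME carries the rest
    },
    stop("unknown omics routing preset: ", routing)
  )
  O
}

#' Score recovered label-feature selections against the planted truth
#'
#' Matches recovered factor columns to planted ones (assignment maximizing
#' patient-factor cosine), translates each label's selected recovered
#' features into planted feature ids, and computes precision/recall against
#' the label's planted set; also reports the matched factor cosines.
#'
#' @param truth `synthetic_truth` from [generate_cohort()].
#' @param decomp `cp_decomposition` of the (noisy) tensor.
#' @param selections Result of [select_all_labels()] on `decomp$C_p`.
#' @return List: per-label `precision`/`recall`, their means, the
#'   column `matching` (recovered column per planted feature) and
#'   `mean_cosine` of the patient-factor match.
#' @export
evaluate_feature_recovery <- function(truth, decomp, selections) {
  mt <- match_factors(decomp$C_p, truth$P)
  # planted feature id for each recovered column (inverse of the matching)
  planted_of <- integer(ncol(decomp$C_p))
  planted_of[mt$perm] <- seq_along(mt$perm)
  prec <- rec <- stats::setNames(numeric(length(selections$selections)),
                                 names(selections$selections))
  for (lab in names(selections$selections)) {
    sel <- selections$selections[[lab]]$selected
    hit <- planted_of[sel]
    hit <- hit[hit > 0]
    planted <- truth$label_features[[lab]]
    prec[lab] <- if (length(sel) > 0) length(intersect(hit, planted)) / length(sel) else 0
    rec[lab] <- if (length(planted) > 0) length(intersect(hit, planted)) / length(planted) else 1
  }
  list(precision = prec, recall = rec,
       mean_precision = mean(prec), mean_recall = mean(rec),
       matching = mt$perm, mean_cosine = mt$mean_cosine)
}

#' Write a synthetic cohort as a raw multi-omics fixture file set
#'
#' Materializes the cohort as the external files the IO layer consumes:
#' a raw gene-expression TSV, a methylation probe matrix plus manifest, a
#' miRNA matrix plus target map, a gene annotation TSV, and a sample label
#' TSV, constructed so the standard pipeline (probe/bundle aggregation,
#' log2 + quantile normalization, min-max scaling, stacking) approximately
#' reproduces the generated tensor. Expression-scale values are laid out as
#' `2^(10*t) - 1` so the log2 step recovers `10*t`; each gene gets two
#' promoter probes carrying its methylation value; miRNAs map 1:1 to genes
#' except every tenth gene, which is covered by a two-miRNA bundle (both
#' members carry the bundle value, so the geometric mean is exact).
#'
#' @param cohort Result of [generate_cohort()] (needs 3 omics GE/ME/MI).
#' @param dir Output directory (created).
#' @return Named list of the file paths written, invisibly.
#' @export
make_fixture_files <- function(cohort, dir) {
  tensor <- cohort$tensor
  stopifnot(identical(dimnames(tensor)[[3]][1:3], c("GE", "ME", "MI")))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- dimnames(tensor)[[1]]
  n <- length(genes)

  # gene annotation: alternating strand, protein_coding, TSS spaced out
  tss <- 10000L * seq_len(n) + 5000L
  strand <- rep(c("+", "-"), length.out = n)
  ann <- data.frame(gene_id = genes, chrom = "chr1", strand = strand,
                    tss = tss, biotype = "protein_coding")
  p_ann <- file.path(dir, "genes.tsv")
  utils::write.table(ann, p_ann, sep = "\t", quote = FALSE, row.names = FALSE)

  # expression: invert the log2 step
  ge <- 2^(10 * tensor[, , "GE"]) - 1
  p_ge <- file.path(dir, "expression.tsv")
  write_omics_matrix(ge, p_ge, id_col = "gene_id")

  # methylation: two probes per gene inside the strand-aware promoter window
  beta <- tensor[, , "ME"]
  probe_ids <- c(paste0("cg_", genes, "_a"), paste0("cg_", genes, "_b"))
  offs_a <- ifelse(strand == "+", -500L, 500L)
  offs_b <- ifelse(strand == "+", -1500L, 1500L)
  manifest <- data.frame(probe_id = probe_ids, chrom = "chr1",
                         pos = c(tss + offs_a, tss + offs_b))
  probes <- rbind(beta, beta)
  rownames(probes) <- probe_ids
  p_probes <- file.path(dir, "methylation_probes.tsv")
  p_manifest <- file.path(dir, "probe_manifest.tsv")
  write_omics_matrix(probes, p_probes, id_col = "probe_id")
  utils::write.table(manifest, p_manifest, sep = "\t", quote = FALSE, row.names = FALSE)

  # miRNA: 1:1 bundles, plus a second miRNA for every 10th gene
  mi <- 2^(10 * tensor[, , "MI"]) - 1
  mirna1 <- paste0("mir-", seq_len(n), "-a")
  extra <- seq(10, n, by = 10)
  mirna_mat <- rbind(mi, mi[extra, , drop = FALSE])
  rownames(mirna_mat) <- c(mirna1, paste0("mir-", extra, "-b"))
  tmap <- data.frame(mirna_id = c(mirna1, paste0("mir-", extra, "-b")),
                     gene_id = c(genes, genes[extra]))
  p_mirna <- file.path(dir, "mirna.tsv")
  p_tmap <- file.path(dir, "mirna_targets.tsv")
  write_omics_matrix(mirna_mat, p_mirna, id_col = "mirna_id")
  utils::write.table(tmap, p_tmap, sep = "\t", quote = FALSE, row.names = FALSE)

  lab <- data.frame(sample_id = names(cohort$labels), label = unname(cohort$labels))
  p_lab <- file.path(dir, "labels.tsv")
  utils::write.table(lab, p_lab, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- cohort$truth
  jsonlite::write_json(list(label_features = truth$label_features,
                            signal = truth$signal, noise_sd = truth$noise_sd,
                            omics_routing = if (is.matrix(truth$omics_routing)) "custom" else truth$omics_routing,
                            seed = truth$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(expression = p_ge, methylation_probes = p_probes,
                 probe_manifest = p_manifest, mirna = p_mirna,
                 mirna_targets = p_tmap, annotation = p_ann, labels = p_lab))
}
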