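#' Quantile-normalize a matrix across sample columns
#'
#' Classic quantile normalization (as used for expression arrays): every
#' column is re-assigned the across-column means of the order statistics, so
#' all columns end with an identical multiset of values. Ties within a column
#' receive the mean of the order-statistic means across the tied ranks.
#'
#' @param x Numeric matrix (features x samples), no missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(x) {
  if (anyNA(x)) stop("quantile_normalize expects a complete matrix; impute first")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attributes(out) <- attributes(x)
  out
}

#' Log-transform and quantile-normalize an omics matrix
#'
#' Applies `log2(x + 1)` (the pseudocount keeps zero counts finite), then
#' column-wise quantile normalization across samples. Intended for
#' expression-scale layers; methylation beta values are quantile-normalized
#' without the log step.
#'
#' @param x Non-negative numeric matrix (features x samples).
#' @return Normalized matrix, same shape and attributes.
#' @export
log2_quantile_normalize <- function(x) {
  if (anyNA(x)) stop("log2_quantile_normalize expects a complete matrix")
  if (any(x < 0)) stop("negative values: expression-scale input must be non-negative")
  quantile_normalize(log2(x + 1))
}

#' Aggregate methylation probes into gene-level promoter values
#'
#' For each annotated gene a strand-aware promoter window is taken: the 2 kb
#' upstream of the transcription start site, i.e. `[TSS - window, TSS]` on the
#' `+` strand and `[TSS, TSS + window]` on the `-` strand (1-based inclusive).
#' The gene's per-sample value is the arithmetic mean of the non-missing beta
#' values of the probes inside the window. Probes missing in every sample are
#' dropped first; genes with no probe in their window are absent from the
#' output (they cannot be represented on the methylation slice).
#'
#' @param probes Probe x sample beta matrix (values in `[0,1]` or `NA`).
#' @param manifest data.frame `probe_id, chrom, pos` (1-based).
#' @param annotation data.frame `gene_id, chrom, strand, tss, biotype`.
#' @param window Promoter window size in bp upstream of the TSS.
#' @return `omics_matrix` (gene x sample) of mean promoter betas; cells are
#'   `NA` where every window probe is missing for that sample.
#' @export
methylation_to_gene <- function(probes, manifest, annotation, window = 2000L) {
  if (any(probes < 0 | probes > 1, na.rm = TRUE))
    stop("beta values must lie in [0,1]")
  keep <- rowSums(!is.na(probes)) > 0
  probes <- probes[keep, , drop = FALSE]
  manifest <- manifest[manifest$probe_id %in% rownames(probes), , drop = FALSE]
  pos <- stats::setNames(manifest$pos, manifest$probe_id)
  chrom <- stats::setNames(manifest$chrom, manifest$probe_id)

  res <- matrix(NA_real_, nrow = 0, ncol = ncol(probes))
  rows <- character(0)
  for (g in seq_len(nrow(annotation))) {
    gene <- annotation$gene_id[g]
    tss <- annotation$tss[g]
    win <- if (annotation$strand[g] == "+") c(tss - window, tss) else c(tss, tss + window)
    in_win <- names(pos)[chrom == annotation$chrom[g] & pos >= win[1] & pos <= win[2]]
    if (length(in_win) == 0) next
    block <- probes[in_win, , drop = FALSE]
    res <- rbind(res, colMeans(block, na.rm = TRUE))
    rows <- c(rows, gene)
  }
  if (length(rows) == 0) stop("no gene has a methylation probe in its promoter window")
  res[is.nan(res)] <- NA_real_
  dimnames(res) <- list(rows, colnames(probes))
  omics_matrix(res, omics_name = "ME", kind = "methylation_gene")
}

#' Aggregate miRNA expression into gene-level bundle values
#'
#' All miRNAs targeting a gene form its bundle; the gene's per-sample value is
#' the bundle's geometric mean computed on a log scale with pseudocount,
#' `exp(mean(log(x + 1))) - 1` (default), or the plain arithmetic mean.
#' miRNAs with zero expression in every sample are excluded first. Genes in
#' `gene_ids` that no retained miRNA targets receive 0 (a silent bundle).
#'
#' @param mirna miRNA x sample expression matrix, non-negative.
#' @param target_map Named list: miRNA ID -> character vector of target genes.
#' @param gene_ids Genes to represent in the output (rows, in this order).
#' @param mode `"geometric"` or `"arithmetic"` bundle mean.
#' @return `omics_matrix` (gene x sample).
#' @export
mirna_to_gene <- function(mirna, target_map, gene_ids,
                          mode = c("geometric", "arithmetic")) {
  mode <- match.arg(mode)
  if (length(target_map) == 0) stop("empty miRNA target map")
  if (any(mirna < 0, na.rm = TRUE)) stop("miRNA expression must be non-negative")
  expressed <- rowSums(mirna, na.rm = TRUE) > 0
  mirna <- mirna[expressed, , drop = FALSE]
  target_map <- target_map[names(target_map) %in% rownames(mirna)]

  # invert: gene -> miRNAs targeting it
  pairs_g <- unlist(target_map, use.names = FALSE)
  pairs_m <- rep(names(target_map), lengths(target_map))
  by_gene <- split(pairs_m, pairs_g)

  out <- matrix(0, nrow = length(gene_ids), ncol = ncol(mirna),
                dimnames = list(gene_ids, colnames(mirna)))
  for (gene in intersect(gene_ids, names(by_gene))) {
    block <- mirna[by_gene[[gene]], , drop = FALSE]
    out[gene, ] <- if (mode == "geometric") {
      exp(colMeans(log(block + 1))) - 1
    } else {
      colMeans(block)
    }
  }
  omics_matrix(out, omics_name = "MI", kind = "mirna_gene")
}

#' Select the common usable gene set across the three layers
#'
#' Keeps genes that are (i) protein-coding per the annotation, (ii) present in
#' all supplied gene-centric matrices, and (iii) non-missing on the
#' methylation slice in at least `1 - max_missing_fraction` of samples (genes
#' whose promoter methylation is missing in more than 80% of samples, by
#' default, carry too little signal). Output order is lexicographic.
#'
#' @param matrices Named list of gene x sample matrices; the methylation layer
#'   is identified by `meth_name`.
#' @param annotation Gene annotation data.frame (needs `gene_id`, `biotype`).
#' @param max_missing_fraction Maximum tolerated missing fraction on the
#'   methylation slice.
#' @param meth_name Name of the methylation element of `matrices`.
#' @return Sorted character vector of retained gene IDs.
#' @export
filter_genes <- function(matrices, annotation, max_missing_fraction = 0.8,
                         meth_name = "ME") {
  coding <- annotation$gene_id[annotation$biotype == "protein_coding"]
  common <- Reduce(intersect, lapply(matrices, rownames))
  keep <- intersect(common, coding)
  if (meth_name %in% names(matrices)) {
    meth <- matrices[[meth_name]]
    miss <- rowMeans(is.na(meth[intersect(keep, rownames(meth)), , drop = FALSE]))
    keep <- intersect(keep, names(miss)[miss <= max_missing_fraction])
  }
  if (length(keep) == 0) stop("no gene passes the coding/missingness filters")
  sort(keep, method = "radix")
}

#' Min-max scale one omics slice to [0, 1]
#'
#' Uses the global minimum and maximum of the whole slice (not per gene):
#' scaling exists to stop a large-valued layer from drowning the others in the
#' tensor fit, so within-layer magnitude structure must be preserved. A
#' constant slice has no range and maps to all zeros.
#'
#' @param x Numeric matrix, no missing values.
#' @return Matrix with values in `[0,1]`.
#' @export
minmax_scale_slice <- function(x) {
  if (anyNA(x)) stop("minmax_scale_slice expects a complete matrix")
  rng <- range(x)
  out <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
  attr(out, "scale_range") <- rng
  out
}

#' Impute residual missing values by per-gene mean
#'
#' Within one omics slice, a missing cell takes its gene's row mean over the
#' observed samples; a gene observed nowhere takes 0.
#'
#' @param x Numeric matrix.
#' @return Complete matrix.
#' @export
impute_gene_mean <- function(x) {
  if (!anyNA(x)) return(x)
  rm <- rowMeans(x, na.rm = TRUE)
  rm[is.nan(rm)] <- 0
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- rm[idx[, 1]]
  x
}

#' Stack gene-centric omics matrices into a tensor
#'
#' All matrices must share identical gene and sample axes (same order).
#' Residual missing cells are imputed by per-gene mean within their slice,
#' then each slice is min-max scaled to `[0,1]`, and the slices are stacked on
#' a third axis.
#'
#' @param matrices Named list of gene x sample matrices (one per omics layer).
#' @param scale Logical; min-max scale each slice (default TRUE).
#' @return An `omics_tensor`: 3-d array genes x samples x omics with dimnames,
#'   and attribute `scale_ranges` (per-slice min/max before scaling).
#' @export
assemble_tensor <- function(matrices, scale = TRUE) {
  if (length(matrices) < 1) stop("need at least one omics matrix")
  nm <- names(matrices)
  if (is.null(nm) || any(!nzchar(nm))) stop("matrices must be a named list (omics names)")
  g0 <- rownames(matrices[[1]]); s0 <- colnames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), g0) || !identical(colnames(m), s0))
      stop("all omics matrices must share identical gene and sample axes")
  }
  ranges <- vector("list", length(matrices))
  arr <- array(NA_real_, dim = c(length(g0), length(s0), length(matrices)),
               dimnames = list(g0, s0, nm))
  for (k in seq_along(matrices)) {
    slice <- impute_gene_mean(unclass(matrices[[k]]))
    if (scale) {
      slice <- minmax_scale_slice(slice)
      ranges[[k]] <- attr(slice, "scale_range")
    }
    arr[, , k] <- slice
  }
  structure(arr, scale_ranges = stats::setNames(ranges, nm),
            class = c("omics_tensor", "array"))
}

#' Write a tensor as TSV slices plus a JSON sidecar
#'
#' One `slice_<omics>.tsv` per layer plus `tensor.json` holding the axis
#' labels and dimensions, so a tensor directory is self-describing.
#'
#' @param tensor `omics_tensor`.
#' @param dir Output directory (created if needed).
#' @param meta Optional named list merged into the sidecar (e.g. config hash).
#' @return `dir`, invisibly.
#' @export
write_tensor <- function(tensor, dir, meta = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dn <- dimnames(tensor)
  for (k in seq_len(dim(tensor)[3])) {
    m <- tensor[, , k]
    write_omics_matrix(m, file.path(dir, paste0("slice_", dn[[3]][k], ".tsv")),
                       id_col = "gene_id")
  }
  side <- c(list(gene_ids = dn[[1]], sample_ids = dn[[2]], omics_names = dn[[3]],
                 dim = dim(tensor)), meta)
  jsonlite::write_json(side, file.path(dir, "tensor.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a tensor written by [write_tensor()]
#'
#' @param dir Tensor directory.
#' @return `omics_tensor`.
#' @export
read_tensor <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "tensor.json"), simplifyVector = TRUE)
  slices <- lapply(side$omics_names, function(o) {
    m <- read_omics_matrix(file.path(dir, paste0("slice_", o, ".tsv")))
    unclass(m)[side$gene_ids, side$sample_ids, drop = FALSE]
  })
  arr <- array(unlist(slices, use.names = FALSE),
               dim = c(length(side$gene_ids), length(side$sample_ids), length(side$omics_names)),
               dimnames = list(side$gene_ids, side$sample_ids, side$omics_names))
  structure(arr, class = c("omics_tensor", "array"))
}
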