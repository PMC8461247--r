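#' Read a feature-by-sample omics matrix from TSV
#'
#' Parses a tab-delimited table whose first column holds feature identifiers
#' (genes, methylation probes or miRNAs) and whose header row holds sample
#' identifiers. Missing cells may be empty or `"NA"`; both are read as `NA`
#' and preserved. Any other non-numeric cell is an error that names the
#' offending row and column, as is any duplicated feature identifier.
#'
#' @param path Path to the TSV file.
#' @param kind One of `"expression"`, `"methylation_probe"`, `"mirna"`;
#'   recorded as provenance on the returned object.
#' @return An `omics_matrix`: a numeric matrix (features x samples) with
#'   `dimnames`, plus attributes `omics_name` and `kind`.
#' @export
read_omics_matrix <- function(path, kind = c("expression", "methylation_probe", "mirna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("matrix TSV needs a feature-ID column plus >=1 sample column: ", path)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate feature IDs in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample IDs in header of ", path)
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    col <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell in %s at row '%s', column '%s': '%s'",
                   path, ids[bad[1]], samples[j], col[bad[1]]))
    }
    vals[, j] <- num
  }
  omics_matrix(vals, omics_name = kind, kind = kind)
}

#' Construct an omics matrix object
#'
#' @param values Numeric matrix, features in rows, samples in columns; must
#'   carry unique row and column names.
#' @param omics_name Label for the omics layer (e.g. `"GE"`, `"ME"`, `"MI"`).
#' @param kind Provenance tag; defaults to `omics_name`.
#' @return The matrix with class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics_name, kind = omics_name) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_matrix needs row (feature) and column (sample) names")
  if (anyDuplicated(rownames(values))) stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  structure(values, omics_name = omics_name, kind = kind,
            class = c("omics_matrix", class(values)))
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_omics_matrix()]: the written file re-reads to a
#' value-identical matrix (missing values become `NA` cells).
#'
#' @param x Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name for the feature-ID column.
#' @export
write_omics_matrix <- function(x, path, id_col = "feature_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_col, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED or TSV)
#'
#' Accepts either 6-column BED (`chrom, start, end, name, biotype, strand`,
#' 0-based half-open) or a header TSV with columns
#' `gene_id, chrom, strand, tss, biotype` (1-based TSS). BED records are
#' converted to a 1-based TSS using the strand (start+1 on `+`, end on `-`).
#'
#' @param path File path.
#' @return data.frame with columns `gene_id, chrom, strand, tss, biotype`.
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (identical(fields[1], "gene_id")) {
    ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    need <- c("gene_id", "chrom", "strand", "tss", "biotype")
    if (!all(need %in% colnames(ann)))
      stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
    ann <- ann[, need]
  } else {
    bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "")
    if (ncol(bed) < 6) stop("BED annotation needs 6 columns")
    colnames(bed)[1:6] <- c("chrom", "start", "end", "gene_id", "biotype", "strand")
    tss <- ifelse(bed$strand == "+", bed$start + 1L, bed$end)
    ann <- data.frame(gene_id = bed$gene_id, chrom = bed$chrom,
                      strand = bed$strand, tss = as.integer(tss),
                      biotype = bed$biotype, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id in annotation")
  if (!all(ann$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(ann$tss < 1)) stop("tss must be >= 1 (1-based)")
  ann
}

#' Read a methylation probe manifest
#'
#' @param path TSV with columns `probe_id, chrom, pos` (1-based position).
#' @return data.frame with those columns.
#' @export
read_probe_manifest <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% colnames(m)))
    stop("probe manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m$probe_id)) stop("duplicate probe_id in manifest")
  m$pos <- as.integer(m$pos)
  m[, need]
}

#' Read a miRNA-to-target-gene map
#'
#' One `(mirna_id, gene_id)` pair per line, tab-separated, with a header.
#' miRNAs whose target set would be empty are not representable and hence
#' never retained.
#'
#' @param path TSV path.
#' @return Named list: one character vector of target gene IDs per miRNA.
#' @export
read_mirna_targets <- function(path) {
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  if (ncol(m) < 2) stop("target map needs columns mirna_id, gene_id")
  colnames(m)[1:2] <- c("mirna_id", "gene_id")
  m <- m[!is.na(m$mirna_id) & !is.na(m$gene_id) & nzchar(m$gene_id), , drop = FALSE]
  if (nrow(m) == 0) stop("empty miRNA target map: ", path)
  split(m$gene_id, m$mirna_id)
}

#' Read a sample label table
#'
#' @param path TSV with columns `sample_id, label`.
#' @return Named character vector: labels indexed by sample ID.
#' @export
read_labels <- function(path) {
  t <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "",
                         colClasses = "character")
  if (ncol(t) < 2) stop("label TSV needs columns sample_id, label")
  if (anyDuplicated(t[[1]])) stop("duplicate sample_id in label table")
  stats::setNames(t[[2]], t[[1]])
}

#' Intersect sample IDs across omics layers
#'
#' Only samples measured in every layer enter the tensor. The intersection is
#' returned in lexicographic order so downstream artifacts are reproducible
#' across platforms; per-layer dropped-sample counts are reported via message.
#'
#' @param matrices List (>= 2) of matrices with sample IDs as column names.
#' @return Character vector of common sample IDs, sorted.
#' @export
match_samples <- function(matrices) {
  if (length(matrices) < 2) stop("need >= 2 omics tables to match samples")
  sets <- lapply(matrices, colnames)
  common <- Reduce(intersect, sets)
  if (length(common) == 0) stop("no samples shared across all omics layers")
  common <- sort(common, method = "radix")
  dropped <- vapply(sets, function(s) length(setdiff(s, common)), integer(1))
  nm <- names(matrices)
  if (is.null(nm)) nm <- paste0("omics", seq_along(matrices))
  message("matched ", length(common), " samples; dropped per layer: ",
          paste(sprintf("%s=%d", nm, dropped), collapse = ", "))
  common
}

#' Screen a categorical attribute for supervised use
#'
#' A label attribute is usable when it has at least 2 and fewer than
#' `max_classes` distinct classes and its rarest class holds at least
#' `min_class_fraction` of the samples (strongly biased attributes are
#' excluded). A pure predicate: no randomness, same verdict for same input.
#'
#' @param labels Named character vector (sample -> label); `NA` labels are
#'   ignored.
#' @param max_classes Exclusive upper bound on the number of classes.
#' @param min_class_fraction Minimum allowed share of the rarest class.
#' @return List with `accepted` (logical), `reason` (string, `NA` if
#'   accepted), `n_classes`, and the class `counts`.
#' @export
filter_label_attribute <- function(labels, max_classes = 5L,
                                   min_class_fraction = 0.05) {
  labels <- labels[!is.na(labels)]
  counts <- table(labels)
  k <- length(counts)
  verdict <- function(ok, reason) {
    list(accepted = ok, reason = if (ok) NA_character_ else reason,
         n_classes = k, counts = counts)
  }
  if (k < 2) return(verdict(FALSE, "fewer than 2 classes"))
  if (k >= max_classes)
    return(verdict(FALSE, sprintf("%d classes, need fewer than %d", k, max_classes)))
  frac <- min(counts) / sum(counts)
  if (frac < min_class_fraction)
    return(verdict(FALSE, sprintf("high sample bias: rarest class holds %.3f < %.3f of samples",
                                  frac, min_class_fraction)))
  verdict(TRUE, NA_character_)
}
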