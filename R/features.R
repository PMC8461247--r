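# One-vs-rest L1 feature selection on the patient factor, and argmax
# assignment of genes and omics layers to latent features.

#' Lasso by cyclic coordinate descent on the unnormalized objective
#'
#' Minimizes `sum_i (y_i - sum_f z_if w_f)^2 + alpha * sum_f |w_f|` — note:
#' plain residual sum of squares, no 1/M factor, no intercept unless
#' requested. The coordinate update is the soft threshold
#' `w_f = S(z_f' r_f, alpha/2) / (z_f' z_f)` with `r_f` the partial residual.
#'
#' @param Z Design matrix (samples x features).
#' @param y Numeric response.
#' @param alpha Non-negative L1 penalty weight.
#' @param intercept Fit an unpenalized intercept (default FALSE, matching the
#'   bare objective).
#' @param tol Convergence tolerance on the largest coordinate change.
#' @param max_iter Maximum full passes.
#' @return List `w` (weights), `intercept`, `n_iter`, `converged`.
#' @export
lasso_cd <- function(Z, y, alpha, intercept = FALSE, tol = 1e-6,
                     max_iter = 10000L) {
  if (alpha < 0) stop("alpha must be >= 0")
  Z <- as.matrix(Z)
  p <- ncol(Z)
  w <- numeric(p)
  b0 <- 0
  zz <- colSums(Z^2)
  r <- y  # residual for w = 0, b0 = 0
  soft <- function(x, t) sign(x) * max(abs(x) - t, 0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    delta <- 0
    if (intercept) {
      new0 <- b0 + mean(r)
      r <- r - (new0 - b0)
      delta <- max(delta, abs(new0 - b0))
      b0 <- new0
    }
    for (f in seq_len(p)) {
      if (zz[f] == 0) next
      rho <- sum(Z[, f] * r) + zz[f] * w[f]
      new <- soft(rho, alpha / 2) / zz[f]
      if (new != w[f]) {
        r <- r - Z[, f] * (new - w[f])
        delta <- max(delta, abs(new - w[f]))
        w[f] <- new
      }
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(w = w, intercept = b0, n_iter = it, converged = converged)
}

#' Select label-specific features by one-vs-rest L1 regression
#'
#' Regresses the indicator of one label (1 for its samples, 0 for all others)
#' on the patient-factor loadings `C_p` with an L1 penalty, then keeps the
#' top 20% of nonzero-weight features ranked by `|w|` (ceiling, at least one
#' when any weight survives; ties broken toward the lower feature index).
#'
#' @param C_p Patient factor matrix (samples x R), rows named by sample ID.
#' @param labels Named character vector sample -> label covering all rows.
#' @param label The label whose features to select.
#' @param alpha L1 penalty weight.
#' @param top_fraction Fraction of nonzero features kept (default 0.2).
#' @param intercept Passed to [lasso_cd()].
#' @param penalty `"l1"` (default) or `"l2"`; ridge is provided for the
#'   regularizer comparison and selects by `|w|` rank alone (no sparsity).
#' @return A `feature_selection`: list with `label`, `alpha`, `weights`,
#'   `nonzero` (indices), `selected` (indices, top 20%), `n_samples_pos`.
#' @export
l1_select <- function(C_p, labels, label, alpha = 0.01, top_fraction = 0.2,
                      intercept = FALSE, penalty = c("l1", "l2")) {
  penalty <- match.arg(penalty)
  if (alpha < 0) stop("alpha must be >= 0")
  labels <- align_labels(labels, rownames(C_p))
  y <- as.numeric(labels == label)
  if (sum(y) < 2) stop("label '", label, "' has fewer than 2 samples")
  if (penalty == "l1") {
    fit <- lasso_cd(C_p, y, alpha, intercept = intercept)
    w <- fit$w
  } else {
    # ridge closed form on the same unnormalized objective
    R <- ncol(C_p)
    w <- drop(solve(crossprod(C_p) + diag(alpha, R), crossprod(C_p, y)))
  }
  nonzero <- which(abs(w) > 0)
  selected <- integer(0)
  if (length(nonzero) > 0) {
    k <- max(1L, ceiling(top_fraction * length(nonzero)))
    ord <- nonzero[order(-abs(w[nonzero]), nonzero)]  # ties -> lower index
    selected <- sort(ord[seq_len(min(k, length(ord)))])
  }
  structure(list(label = label, alpha = alpha, weights = w,
                 nonzero = nonzero, selected = selected,
                 n_samples_pos = sum(y)),
            class = "feature_selection")
}

align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels)) && !is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing) > 0)
      stop("samples without a label: ", paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[sample_ids]
  }
  labels
}

#' Run one-vs-rest selection for every label
#'
#' @inheritParams l1_select
#' @return List with `selections` (per label, named), `union` (sorted union
#'   of selected feature indices), `alpha`.
#' @export
select_all_labels <- function(C_p, labels, alpha = 0.01, top_fraction = 0.2,
                              intercept = FALSE, penalty = "l1") {
  labels <- align_labels(labels, rownames(C_p))
  classes <- sort(unique(as.character(labels[!is.na(labels)])))
  if (length(classes) < 2) stop("need >= 2 label classes for one-vs-rest selection")
  sel <- lapply(classes, function(cl)
    l1_select(C_p, labels, cl, alpha = alpha, top_fraction = top_fraction,
              intercept = intercept, penalty = penalty))
  names(sel) <- classes
  union <- sort(unique(unlist(lapply(sel, `[[`, "selected"))))
  list(selections = sel, union = union, alpha = alpha)
}

#' Assign each gene to its dominant latent feature
#'
#' A gene belongs to the feature where its gene-factor weight is maximal
#' (ties, including all-zero rows, resolve to the lowest index; all-zero rows
#' are flagged). With per-label selections, each label's gene set collects
#' the genes whose feature lies in that label's selected set; gene sets may
#' overlap across labels.
#'
#' @param C_g Gene factor matrix (genes x R), rows named by gene ID.
#' @param selections Optional result of [select_all_labels()].
#' @return A `gene_assignment`: list with `feature` (named integer vector,
#'   gene -> feature index), `ambiguous` (genes with all-zero rows), and
#'   `label_genes` (list label -> gene IDs) when selections are given.
#' @export
assign_genes <- function(C_g, selections = NULL) {
  feat <- max.col(C_g, ties.method = "first")
  names(feat) <- rownames(C_g)
  zero <- rowSums(abs(C_g)) == 0
  if (any(zero))
    warning(sum(zero), " gene(s) have all-zero factor rows; assigned to feature 1")
  label_genes <- NULL
  if (!is.null(selections)) {
    label_genes <- lapply(selections$selections, function(s)
      names(feat)[feat %in% s$selected])
  }
  structure(list(feature = feat, ambiguous = names(feat)[zero],
                 label_genes = label_genes),
            class = "gene_assignment")
}

#' Assign each latent feature to its dominant omics layer
#'
#' Per feature, the omics layer with the largest omics-factor loading; exact
#' ties (including uniform columns) resolve to the first layer in tensor
#' order and are flagged as ambiguous.
#'
#' @param C_o Omics factor matrix (K x R), rows named by omics layer.
#' @return List `omics` (character vector feature -> layer name, or indices
#'   when `C_o` has no rownames) and `ambiguous` (logical per feature).
#' @export
assign_omics <- function(C_o) {
  idx <- apply(C_o, 2, which.max)
  amb <- apply(C_o, 2, function(col) sum(col == max(col)) > 1)
  layer <- if (!is.null(rownames(C_o))) rownames(C_o)[idx] else idx
  names(layer) <- colnames(C_o)
  names(amb) <- colnames(C_o)
  list(omics = layer, ambiguous = amb)
}

#' Write per-label feature weights and gene assignments as TSV/JSON
#'
#' @param selections Result of [select_all_labels()].
#' @param assignment Result of [assign_genes()].
#' @param omics_map Result of [assign_omics()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_selection <- function(selections, assignment, omics_map, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(selections$selections)) {
    s <- selections$selections[[nm]]
    df <- data.frame(feature = seq_along(s$weights), weight = s$weights,
                     selected = seq_along(s$weights) %in% s$selected)
    utils::write.table(df, file.path(dir, paste0("weights_", gsub("[^A-Za-z0-9_.-]", "_", nm), ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  feat <- assignment$feature
  lab_of_gene <- vapply(names(feat), function(g) {
    labs <- names(assignment$label_genes)[vapply(assignment$label_genes,
                                                 function(gs) g %in% gs, logical(1))]
    paste(labs, collapse = ",")
  }, character(1))
  df <- data.frame(gene_id = names(feat), feature = unname(feat),
                   omics = unname(omics_map$omics[feat]),
                   labels = unname(lab_of_gene))
  utils::write.table(df, file.path(dir, "gene_assignment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(alpha = selections$alpha,
                  union_features = selections$union,
                  per_label = lapply(selections$selections, function(s)
                    list(n_nonzero = length(s$nonzero),
                         n_selected = length(s$selected),
                         selected = s$selected)))
  jsonlite::write_json(summary, file.path(dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
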