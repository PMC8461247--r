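# Cross-validated scoring of selected features: stratified k-fold, MLP
# classifier, macro-averaged F1; transductive (decompose once, CV the
# classifier) and strict (refit normalization, decomposition and selection on
# training folds only) protocols; omics-ablation comparisons.

#' Evaluation configuration
#'
#' @param n_folds Number of cross-validation folds.
#' @param seed Seed controlling fold assignment and classifier init.
#' @param mode `"strict"` (split before any normalization or selection;
#'   default) or `"transductive"` (decompose once on all samples, CV only the
#'   classifier).
#' @param omics_subset Omics layers fed to the classifier (e.g.
#'   `c("GE","ME")`); `NULL` means all layers of the tensor.
#' @param input_kind `"gene_values"` (selected feature genes' scaled omics
#'   values; default) or `"patient_features"` (C_p loadings at selected
#'   features, held-out samples projected by NNLS).
#' @param rank,alpha,n_starts,max_iter Decomposition/selection settings used
#'   by the strict protocol.
#' @param hidden,epochs MLP size and training length.
#' @param mirna_mode Bundle mean passed through to the pipeline.
#' @return Named list of settings.
#' @export
eval_config <- function(n_folds = 10L, seed = 1L, mode = c("strict", "transductive"),
                        omics_subset = NULL, input_kind = c("gene_values", "patient_features"),
                        rank = 8L, alpha = 0.01, n_starts = 2L, max_iter = 200L,
                        hidden = 100L, epochs = 500L, mirna_mode = "geometric") {
  if (n_folds < 2) stop("n_folds must be >= 2")
  list(n_folds = as.integer(n_folds), seed = as.integer(seed),
       mode = match.arg(mode), omics_subset = omics_subset,
       input_kind = match.arg(input_kind), rank = as.integer(rank),
       alpha = alpha, n_starts = as.integer(n_starts),
       max_iter = as.integer(max_iter), hidden = as.integer(hidden),
       epochs = as.integer(epochs), mirna_mode = mirna_mode)
}

#' Stratified fold assignment
#'
#' Deterministic given `(labels, n_folds, seed)`: within each class, sample
#' order is shuffled with the seed, then dealt round-robin across folds. If a
#' class has fewer members than `n_folds`, the fold count is reduced to the
#' smallest class size (with a warning) so every fold keeps every class.
#'
#' @param labels Character/factor vector of class labels.
#' @param n_folds Requested folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), same length as `labels`.
#' @export
make_folds <- function(labels, n_folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  k <- as.integer(n_folds)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning("smallest class has ", min_class, " samples < ", k,
            " folds; reducing to ", max(2L, min_class), " folds")
    k <- max(2L, as.integer(min_class))
  }
  set.seed(seed %% .Machine$integer.max)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Confusion matrix and macro-averaged F1
#'
#' Macro F1 is the unweighted mean over classes of the per-class F1 (harmonic
#' mean of precision and recall); a class with zero precision+recall
#' denominator contributes 0.
#'
#' @param truth,pred Vectors of true and predicted labels.
#' @param levels Class levels (default: union observed).
#' @return List `confusion` (rows = truth), `precision`, `recall`, `f1`
#'   (per class), `macro_f1`.
#' @export
classification_metrics <- function(truth, pred, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(as.character(truth), as.character(pred))))
  truth <- factor(truth, levels = levels)
  pred <- factor(pred, levels = levels)
  cm <- table(truth = truth, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(confusion = cm, precision = prec, recall = rec, f1 = f1,
       macro_f1 = mean(f1))
}

#' Assemble the classifier input table
#'
#' `input_kind = "gene_values"`: for each sample, the scaled omics values of
#' the selected feature genes, one column per (gene, omics layer) pair
#' restricted to `omics_subset` — this is what enables the omics-ablation
#' comparisons. `input_kind = "patient_features"`: the sample's patient-factor
#' loadings at the selected features.
#'
#' @param tensor `omics_tensor` (genes x samples x omics).
#' @param genes Character vector of selected feature genes.
#' @param omics_subset Layers to include (default all).
#' @param input_kind See [eval_config()].
#' @param C_p Patient factor matrix (needed for `"patient_features"`).
#' @param features Selected feature indices (for `"patient_features"`).
#' @return Numeric matrix samples x columns.
#' @export
build_classifier_input <- function(tensor, genes, omics_subset = NULL,
                                   input_kind = "gene_values",
                                   C_p = NULL, features = NULL) {
  if (input_kind == "patient_features") {
    if (is.null(C_p) || is.null(features)) stop("patient_features input needs C_p and features")
    if (length(features) == 0) stop("no selected features to build classifier input from")
    return(C_p[, features, drop = FALSE])
  }
  if (length(genes) == 0) stop("empty selected gene set")
  layers <- dimnames(tensor)[[3]]
  if (is.null(omics_subset)) omics_subset <- layers
  if (!all(omics_subset %in% layers)) stop("unknown omics layer in subset")
  blocks <- lapply(omics_subset, function(o) {
    m <- t(tensor[genes, , o, drop = TRUE])
    if (length(genes) == 1) m <- matrix(m, ncol = 1, dimnames = list(dimnames(tensor)[[2]], NULL))
    colnames(m) <- paste(genes, o, sep = ".")
    m
  })
  do.call(cbind, blocks)
}

#' Project held-out samples onto fixed gene and omics factors
#'
#' Solves one non-negative least-squares problem per sample for its R
#' loadings, with the gene and omics factors held fixed; used by the strict
#' protocol to map test samples into the training feature space.
#'
#' @param C_g,C_o Fixed factor matrices from a training-set decomposition.
#' @param slices 3-d array (genes x new samples x omics), axes matching
#'   `C_g`/`C_o` rows.
#' @return List `C_p_new` (new samples x R, non-negative) and `residuals`
#'   (per-sample NNLS residual norm).
#' @export
project_samples <- function(C_g, C_o, slices) {
  stopifnot(dim(slices)[1] == nrow(C_g), dim(slices)[3] == nrow(C_o))
  A <- khatri_rao(C_o, C_g)  # (N*K) x R, row index i + (k-1)*N
  m <- dim(slices)[2]
  R <- ncol(C_g)
  out <- matrix(0, m, R, dimnames = list(dimnames(slices)[[2]], colnames(C_g)))
  resid <- numeric(m)
  for (j in seq_len(m)) {
    b <- as.vector(slices[, j, ])
    if (all(b == 0)) next
    fit <- pracma::lsqnonneg(A, b)
    out[j, ] <- fit$x
    resid[j] <- sqrt(max(fit$resid.norm, 0))
  }
  list(C_p_new = out, residuals = resid)
}

#' Cross-validate the MLP on a fixed input table
#'
#' The transductive protocol: the input table (already derived from a single
#' decomposition of all samples) is split into stratified folds and only the
#' classifier is refit per fold.
#'
#' @param inputs Numeric matrix (samples x features), rows named by sample.
#' @param labels Named label vector covering the rows.
#' @param config [eval_config()] list.
#' @return An `eval_result`: per-fold macro F1 (`fold_f1`), `mean_f1`, pooled
#'   `confusion`, per-class `precision`/`recall`/`f1`, `macro_f1_pooled`,
#'   `fold` assignment.
#' @export
cross_validate <- function(inputs, labels, config = eval_config()) {
  labels <- align_labels(labels, rownames(inputs))
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  fold <- make_folds(labels, config$n_folds, config$seed)
  k <- max(fold)
  truth_all <- character(0); pred_all <- character(0)
  fold_f1 <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    fit <- mlp_fit(inputs[tr, , drop = FALSE], labels[tr],
                   hidden = config$hidden, epochs = config$epochs,
                   seed = config$seed + f)
    pred <- as.character(predict(fit, inputs[te, , drop = FALSE]))
    fold_f1[f] <- classification_metrics(labels[te], pred, lev)$macro_f1
    truth_all <- c(truth_all, labels[te]); pred_all <- c(pred_all, pred)
  }
  pooled <- classification_metrics(truth_all, pred_all, lev)
  structure(list(fold_f1 = fold_f1, mean_f1 = mean(fold_f1),
                 confusion = pooled$confusion, precision = pooled$precision,
                 recall = pooled$recall, f1 = pooled$f1,
                 macro_f1_pooled = pooled$macro_f1, fold = fold,
                 mode = "transductive"),
            class = "eval_result")
}

# Quantile-normalization reference learned on training columns, applied to
# held-out columns by rank mapping (columns have the same length = genes).
quantile_reference <- function(train) {
  rowMeans(apply(train, 2, sort))
}

apply_quantile_reference <- function(x, ref) {
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average reference values across tied ranks (fractional ranks)
    lo <- ref[floor(r)]; hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(x)
  out
}

# Normalize one raw gene-centric layer with training-fold statistics only,
# returning the full scaled matrix (train + test columns).
normalize_fold_layer <- function(raw, train_cols, log2_first) {
  train <- raw[, train_cols, drop = FALSE]
  # impute residual missing values from training row means
  train <- impute_gene_mean(train)
  test_cols <- setdiff(colnames(raw), train_cols)
  test <- raw[, test_cols, drop = FALSE]
  if (anyNA(test)) {
    rm <- rowMeans(train)
    idx <- which(is.na(test), arr.ind = TRUE)
    test[idx] <- rm[idx[, 1]]
  }
  if (log2_first) {
    if (any(train < 0) || any(test < 0)) stop("negative values in expression-scale layer")
    train <- log2(train + 1); test <- log2(test + 1)
  }
  ref <- quantile_reference(train)
  train_n <- apply_quantile_reference(train, ref)
  test_n <- if (ncol(test) > 0) apply_quantile_reference(test, ref) else test
  rng <- range(train_n)
  scale01 <- function(m) {
    if (rng[2] > rng[1]) pmin(pmax((m - rng[1]) / (rng[2] - rng[1]), 0), 1) else m * 0
  }
  full <- cbind(scale01(train_n), scale01(test_n))
  full[, colnames(raw), drop = FALSE]
}

#' Strict split-before-normalization cross-validation
#'
#' The leakage-free protocol: folds are split first; normalization statistics
#' (quantile reference, min-max range), the tensor decomposition, the L1
#' feature selection and the gene assignment are all computed on training
#' folds only. Held-out samples are normalized with the training statistics
#' and, for `patient_features` inputs, mapped into the training feature space
#' by non-negative least squares ([project_samples()]).
#'
#' @param raw_matrices Named list of raw (un-normalized) gene-centric
#'   matrices, identical gene and sample axes; names are the omics layers.
#'   Layers named `"ME"` are quantile-normalized without the log2 step.
#' @param labels Named label vector covering the samples.
#' @param config [eval_config()] list (mode is implied strict).
#' @return `eval_result` (as [cross_validate()]) plus `per_fold` details
#'   (selected features and genes per fold).
#' @export
cv_strict <- function(raw_matrices, labels, config = eval_config()) {
  layers <- names(raw_matrices)
  subset <- if (is.null(config$omics_subset)) layers else config$omics_subset
  cv_strict_multi(raw_matrices, labels, config, list(subset))[[1]]
}

# Strict CV over several omics subsets at once: normalization, decomposition,
# selection and gene assignment are fit once per fold and shared; only the
# classifier input/refit differs per subset.
cv_strict_multi <- function(raw_matrices, labels, config, subsets) {
  samples <- colnames(raw_matrices[[1]])
  for (m in raw_matrices) stopifnot(identical(colnames(m), samples))
  labels <- align_labels(labels, samples)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  fold <- make_folds(labels, config$n_folds, config$seed)
  k <- max(fold)
  layers <- names(raw_matrices)
  gene_ids <- rownames(raw_matrices[[1]])
  ns <- length(subsets)

  truth_all <- character(0)
  pred_all <- replicate(ns, character(0), simplify = FALSE)
  fold_f1 <- matrix(0, k, ns)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- fold == f
    tr_cols <- samples[tr]; te_cols <- samples[te]
    scaled <- lapply(seq_along(raw_matrices), function(i)
      normalize_fold_layer(unclass(raw_matrices[[i]]), tr_cols,
                           log2_first = layers[i] != "ME"))
    tens <- array(unlist(scaled, use.names = FALSE),
                  dim = c(length(gene_ids), length(samples), length(layers)),
                  dimnames = list(gene_ids, samples, layers))
    dec <- parafac_nn(tens[, tr_cols, , drop = FALSE], rank = config$rank,
                      seed = config$seed + 37L * f,
                      max_iter = config$max_iter, n_starts = config$n_starts)
    sel <- select_all_labels(dec$C_p, labels[tr], alpha = config$alpha)
    asg <- assign_genes(dec$C_g, sel)
    genes <- sort(unique(unlist(asg$label_genes)))
    if (length(genes) == 0) genes <- names(asg$feature)[asg$feature %in% sel$union]
    proj <- NULL
    if (config$input_kind == "patient_features") {
      if (length(sel$union) == 0) stop("no feature selected in fold ", f)
      proj <- project_samples(dec$C_g, dec$C_o, tens[, te_cols, , drop = FALSE])
    }
    for (s in seq_len(ns)) {
      if (config$input_kind == "gene_values") {
        Xtr <- build_classifier_input(tens[, tr_cols, , drop = FALSE], genes, subsets[[s]])
        Xte <- build_classifier_input(tens[, te_cols, , drop = FALSE], genes, subsets[[s]])
      } else {
        Xtr <- dec$C_p[, sel$union, drop = FALSE]
        Xte <- proj$C_p_new[, sel$union, drop = FALSE]
      }
      fit <- mlp_fit(Xtr, labels[tr], hidden = config$hidden,
                     epochs = config$epochs, seed = config$seed + f)
      pred <- as.character(predict(fit, Xte))
      fold_f1[f, s] <- classification_metrics(labels[te], pred, lev)$macro_f1
      pred_all[[s]] <- c(pred_all[[s]], pred)
    }
    truth_all <- c(truth_all, labels[te])
    per_fold[[f]] <- list(selected_features = sel$union, genes = genes,
                          relative_error = dec$relative_error)
  }
  lapply(seq_len(ns), function(s) {
    pooled <- classification_metrics(truth_all, pred_all[[s]], lev)
    structure(list(fold_f1 = fold_f1[, s], mean_f1 = mean(fold_f1[, s]),
                   confusion = pooled$confusion, precision = pooled$precision,
                   recall = pooled$recall, f1 = pooled$f1,
                   macro_f1_pooled = pooled$macro_f1, fold = fold,
                   per_fold = per_fold, omics_subset = subsets[[s]],
                   mode = "strict"),
              class = "eval_result")
  })
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s cross-validation over %d folds: mean macro F1 = %.4f (pooled %.4f)\n",
              x$mode, length(x$fold_f1), x$mean_f1, x$macro_f1_pooled))
  invisible(x)
}

#' Compare classification across omics subsets
#'
#' Evaluates every non-empty subset of the tensor's omics layers with the
#' same protocol and settings, sharing fold assignment, so differences
#' reflect the information content of the layers.
#'
#' @param raw_matrices As in [cv_strict()] (strict mode), or an
#'   `omics_tensor` plus precomputed `genes` for transductive mode.
#' @param labels Named label vector.
#' @param config [eval_config()].
#' @param genes For transductive mode: the selected feature genes.
#' @return data.frame `subset`, `n_omics`, `mean_f1`, `pooled_f1`.
#' @export
omics_ablation <- function(raw_matrices, labels, config = eval_config(),
                           genes = NULL) {
  layers <- if (is.array(raw_matrices)) dimnames(raw_matrices)[[3]] else names(raw_matrices)
  subsets <- unlist(lapply(seq_along(layers), function(n)
    utils::combn(layers, n, simplify = FALSE)), recursive = FALSE)
  results <- if (is.array(raw_matrices)) {
    lapply(subsets, function(ss) {
      X <- build_classifier_input(raw_matrices, genes, ss)
      cross_validate(X, labels, config)
    })
  } else {
    cv_strict_multi(raw_matrices, labels, config, subsets)
  }
  do.call(rbind, lapply(seq_along(subsets), function(s)
    data.frame(subset = paste(subsets[[s]], collapse = "+"),
               n_omics = length(subsets[[s]]),
               mean_f1 = results[[s]]$mean_f1,
               pooled_f1 = results[[s]]$macro_f1_pooled)))
}
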