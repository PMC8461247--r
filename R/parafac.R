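#' Non-negative PARAFAC (CP) decomposition by HALS
#'
#' Fits the trilinear model `T[i,j,k] = sum_f C_g[i,f] C_p[j,f] C_o[k,f] + e`
#' under non-negativity on all three factor matrices, minimizing the sum of
#' squared residuals by hierarchical alternating least squares (column-wise
#' non-negative ALS updates, which keep the objective non-increasing). The
#' first start is an algebraic generalized-eigenvalue (direct trilinear
#' decomposition) initialization — exact for noise-free tensors of the
#' requested rank, and a strong basin otherwise; the remaining starts are
#' random. The best start by relative reconstruction error is returned. The scale indeterminacy is fixed by normalizing the columns of
#' the gene and omics factors to unit L2 norm, pushing all magnitude into the
#' patient factor, whose loadings feed the downstream regression.
#'
#' @param tensor Non-negative, finite 3-d array (genes x samples x omics).
#' @param rank Number of latent features R (>= 1).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param max_iter Maximum ALS sweeps per start.
#' @param tol Stop when the relative change of the objective drops below this.
#' @param n_starts Number of random restarts.
#' @return A `cp_decomposition`: list with factor matrices `C_g` (N x R),
#'   `C_p` (M x R), `C_o` (K x R), `rank`, `relative_error`
#'   (`||T - That||_F / ||T||_F`; 0 by convention for an all-zero tensor),
#'   `seed`, `n_iter`, `converged`, `error_trace`, `revival_at` (sweeps at
#'   which a collapsed column was restarted; the error trace may step up
#'   there), and `start_errors`.
#' @export
parafac_nn <- function(tensor, rank, seed = 1L, max_iter = 500L,
                       tol = 1e-7, n_starts = 5L) {
  if (!is.array(tensor) || length(dim(tensor)) != 3)
    stop("tensor must be a 3-d array")
  if (any(!is.finite(tensor))) stop("tensor must be finite (no NA/NaN/Inf)")
  if (any(tensor < 0)) stop("tensor must be non-negative")
  if (rank < 1) stop("rank must be >= 1")
  d <- dim(tensor)
  normT <- frobenius(tensor)
  dn <- dimnames(tensor)

  if (normT == 0) {
    zero <- function(n) matrix(0, n, rank)
    res <- list(C_g = zero(d[1]), C_p = zero(d[2]), C_o = zero(d[3]),
                rank = rank, relative_error = 0, seed = seed, n_iter = 0L,
                converged = TRUE, error_trace = numeric(0),
                revival_at = integer(0), start_errors = rep(0, n_starts))
    return(structure(res, class = "cp_decomposition"))
  }

  X1 <- unfold3(tensor, 1)
  X2 <- unfold3(tensor, 2)
  X3 <- unfold3(tensor, 3)
  normT2 <- normT^2

  best <- NULL
  start_errors <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    # algebraic (generalized-eigenvalue) starts, one slice mixture per
    # start: exact for noise-free tensors of the requested rank, diverse
    # strong basins under noise; the last start stays purely random
    gevd <- if (s < n_starts || n_starts == 1L)
      cp_init_gevd(tensor, X1, X2, X3, rank, seed + s - 1L) else NULL
    set.seed((seed + s - 1L) %% .Machine$integer.max)
    if (!is.null(gevd)) {
      A <- gevd$A; B <- gevd$B; C <- gevd$C
    } else {
      A <- matrix(stats::runif(d[1] * rank), d[1], rank)  # genes
      B <- matrix(stats::runif(d[2] * rank), d[2], rank)  # samples
      C <- matrix(stats::runif(d[3] * rank), d[3], rank)  # omics
    }

    trace <- numeric(0)
    revival_at <- integer(0)
    prev <- Inf
    converged <- FALSE
    it <- 0L
    revivals <- 0L
    while (it < max_iter) {
      it <- it + 1L
      A <- hals_update(A, X1, B, C)
      B <- hals_update(B, X2, A, C)
      C <- hals_update(C, X3, A, B)
      # objective after the mode-3 sweep, from cached Gram products
      W <- X3 %*% khatri_rao(B, A)
      V <- crossprod(A) * crossprod(B)
      err2 <- max(normT2 - 2 * sum(C * W) + sum(crossprod(C) * V), 0)
      err <- sqrt(err2) / normT
      trace <- c(trace, err)
      if (is.finite(prev) && abs(prev - err) < tol * max(prev, 1e-12)) {
        # a column that collapsed to zero in any mode explains nothing;
        # restart it along the residual's leading singular direction and
        # keep iterating (at most twice per start)
        dead <- which(colSums(A) * colSums(B) * colSums(C) == 0)
        if (length(dead) > 0 && revivals < 2L && err > tol) {
          revivals <- revivals + 1L
          revival_at <- c(revival_at, it)
          res1 <- X1 - A %*% t(khatri_rao(C, B))
          sv <- svd(res1, nu = 1, nv = 1)
          u <- pmax(sv$u[, 1] * sign(sum(sv$u[, 1])), 0)
          vw <- matrix(sv$v[, 1] * sign(sum(sv$v[, 1])), d[2], d[3])
          svv <- svd(vw, nu = 1, nv = 1)
          p <- pmax(svv$u[, 1] * sign(sum(svv$u[, 1])), 0)
          o <- pmax(svv$v[, 1] * sign(sum(svv$v[, 1])), 0)
          s1 <- (sv$d[1] * svv$d[1])^(1 / 3)
          for (r in dead) {
            A[, r] <- u * s1; B[, r] <- p * s1; C[, r] <- o * s1
          }
          prev <- Inf
          next
        }
        converged <- TRUE
        break
      }
      prev <- err
    }

    fit <- list(A = A, B = B, C = C, err = err, n_iter = it,
                converged = converged, trace = trace, revival_at = revival_at)
    start_errors[s] <- err
    if (is.null(best) || err < best$err) best <- fit
  }

  # unit-norm gene and omics columns; scale goes to the patient factor
  ng <- sqrt(colSums(best$A^2)); no <- sqrt(colSums(best$C^2))
  scale <- ng * no
  nz <- scale > 0
  A <- best$A; B <- best$B; C <- best$C
  A[, nz] <- sweep(A[, nz, drop = FALSE], 2, ng[nz], "/")
  C[, nz] <- sweep(C[, nz, drop = FALSE], 2, no[nz], "/")
  B[, nz] <- sweep(B[, nz, drop = FALSE], 2, scale[nz], "*")
  B[, !nz] <- 0

  fnames <- paste0("f", seq_len(rank))
  dimnames(A) <- list(dn[[1]], fnames)
  dimnames(B) <- list(dn[[2]], fnames)
  dimnames(C) <- list(dn[[3]], fnames)
  structure(list(C_g = A, C_p = B, C_o = C, rank = rank,
                 relative_error = best$err, seed = seed, n_iter = best$n_iter,
                 converged = best$converged, error_trace = best$trace,
                 revival_at = best$revival_at, start_errors = start_errors),
            class = "cp_decomposition")
}

# Direct-trilinear-decomposition (GEVD) initialization: project two random
# slice mixtures onto the leading rank-R subspaces of modes 1 and 2; the
# eigenvectors of G1 %*% solve(G2) recover the mode-1 factor up to scale and
# permutation when the tensor has exact rank R. Columns are sign-fixed,
# clamped to >= 0, and the other modes follow by clamped least squares.
# Returns NULL when the construction is not applicable (rank too large,
# single slice, or a numerically singular mixture).
cp_init_gevd <- function(tensor, X1, X2, X3, rank, seed) {
  d <- dim(tensor)
  if (rank > min(d[1], d[2]) || d[3] < 2) return(NULL)
  out <- tryCatch({
    set.seed(seed %% .Machine$integer.max)
    sv1 <- svd(X1, nu = rank, nv = 0)
    sv2 <- svd(X2, nu = rank, nv = 0)
    UA <- sv1$u; UB <- sv2$u
    S <- lapply(seq_len(d[3]), function(k) crossprod(UA, tensor[, , k] %*% UB))
    w1 <- stats::rnorm(d[3]); w2 <- stats::rnorm(d[3])
    G1 <- Reduce(`+`, Map(`*`, S, w1))
    G2 <- Reduce(`+`, Map(`*`, S, w2))
    eg <- eigen(G1 %*% solve(G2))
    # real basis: complex conjugate pairs contribute their Re and Im parts
    V <- matrix(0, rank, rank)
    r <- 1L
    while (r <= rank) {
      if (abs(Im(eg$values[r])) < 1e-10) {
        V[, r] <- Re(eg$vectors[, r])
        r <- r + 1L
      } else {
        V[, r] <- Re(eg$vectors[, r])
        if (r + 1L <= rank) V[, r + 1L] <- Im(eg$vectors[, r])
        r <- r + 2L
      }
    }
    A <- UA %*% V
    sgn <- ifelse(colSums(A) < 0, -1, 1)
    A <- pmax(sweep(A, 2, sgn, "*"), 0)
    # a column clamped to nothing carries no information; restart it random
    dead <- colSums(A) == 0
    if (any(dead))
      A[, dead] <- matrix(stats::runif(sum(dead) * d[1]), d[1])
    B <- matrix(stats::runif(d[2] * rank), d[2], rank)
    C <- matrix(stats::runif(d[3] * rank), d[3], rank)
    for (i in 1:3) {
      B <- pmax(t(qr.solve(khatri_rao(C, A), t(X2))), 0)
      C <- pmax(t(qr.solve(khatri_rao(B, A), t(X3))), 0)
    }
    list(A = A, B = B, C = C)
  }, error = function(e) NULL)
  out
}

# One HALS sweep over the columns of factor `Fm` for unfolding `X`
# with companion factors U, V (design = khatri_rao(V, U) when
# X = Fm %*% t(khatri_rao(V, U))).
hals_update <- function(Fm, X, U, V) {
  W <- X %*% khatri_rao(V, U)        # n x R
  G <- crossprod(U) * crossprod(V)   # R x R Gram (Hadamard of Grams)
  for (r in seq_len(ncol(Fm))) {
    if (G[r, r] <= 0) {
      Fm[, r] <- 0
      next
    }
    upd <- Fm[, r] + (W[, r] - Fm %*% G[, r]) / G[r, r]
    Fm[, r] <- pmax(upd, 0)
  }
  Fm
}

#' @export
print.cp_decomposition <- function(x, ...) {
  cat(sprintf("Non-negative CP decomposition: rank %d, %d genes x %d samples x %d omics\n",
              x$rank, nrow(x$C_g), nrow(x$C_p), nrow(x$C_o)))
  cat(sprintf("relative error %.6g after %d sweeps (%s), seed %d\n",
              x$relative_error, x$n_iter,
              if (isTRUE(x$converged)) "converged" else "max_iter reached",
              x$seed))
  invisible(x)
}

#' Write decomposition factors and metadata to a directory
#'
#' Factor matrices become TSV files (rows = axis entities, columns
#' `f1..fR`); rank, seed, error and iteration count go into a JSON sidecar.
#'
#' @param decomp `cp_decomposition`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(decomp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("C_g", "C_p", "C_o")) {
    m <- decomp[[nm]]
    if (is.null(rownames(m))) rownames(m) <- paste0("r", seq_len(nrow(m)))
    write_omics_matrix(m, file.path(dir, paste0(nm, ".tsv")), id_col = "id")
  }
  meta <- decomp[c("rank", "relative_error", "seed", "n_iter", "converged")]
  jsonlite::write_json(meta, file.path(dir, "decomposition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
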