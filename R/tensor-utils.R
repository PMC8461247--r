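# Dense third-order tensor helpers shared by the decomposition code.
# Unfolding convention (column-major): mode-1 unfolding X1[i, j + (k-1)M],
# so X1 = A %*% t(khatri_rao(C, B)) for T = [[A, B, C]].

#' Column-wise Khatri-Rao product
#'
#' For matrices `A` (I x R) and `B` (J x R), returns the (I*J) x R matrix
#' whose r-th column is `kronecker(A[, r], B[, r])` (B index varies fastest).
#'
#' @param A,B Matrices with the same number of columns.
#' @return Matrix of dimension `nrow(A)*nrow(B)` x `ncol(A)`.
#' @export
khatri_rao <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  # row (b + (a-1)*J) holds A[a, ] * B[b, ]
  A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE] *
    B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE]
}

# mode-n unfolding of a 3-d array
unfold3 <- function(x, mode) {
  d <- dim(x)
  switch(mode,
         `1` = matrix(x, d[1], d[2] * d[3]),
         `2` = matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
         `3` = matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]),
         stop("mode must be 1, 2 or 3"))
}

#' Reconstruct a tensor from CP factor matrices
#'
#' Sum of R rank-1 outer products `g_f (x) p_f (x) o_f`.
#'
#' @param C_g,C_p,C_o Factor matrices (genes/samples/omics x R) or a
#'   `cp_decomposition` passed as the first argument.
#' @return 3-d array of dimension `nrow(C_g)` x `nrow(C_p)` x `nrow(C_o)`.
#' @export
reconstruct <- function(C_g, C_p = NULL, C_o = NULL) {
  if (inherits(C_g, "cp_decomposition")) {
    d <- C_g; C_g <- d$C_g; C_p <- d$C_p; C_o <- d$C_o
  }
  x1 <- C_g %*% t(khatri_rao(C_o, C_p))
  array(x1, dim = c(nrow(C_g), nrow(C_p), nrow(C_o)),
        dimnames = list(rownames(C_g), rownames(C_p), rownames(C_o)))
}

frobenius <- function(x) sqrt(sum(x * x))

#' Match recovered factor columns to reference columns
#'
#' Solves the assignment problem maximizing the total cosine similarity
#' between columns of `recovered` and `reference` (sign-free congruence;
#' columns are compared after L2 normalization). Exact enumeration is used
#' for up to 8 columns, a greedy assignment above that.
#'
#' @param recovered,reference Matrices with the same number of columns.
#' @return List: `perm` (recovered column matched to each reference column),
#'   `cosines` (per matched pair), `mean_cosine`.
#' @export
match_factors <- function(recovered, reference) {
  stopifnot(ncol(recovered) == ncol(reference))
  R <- ncol(reference)
  nrm <- function(m) {
    n <- sqrt(colSums(m^2)); n[n == 0] <- 1
    sweep(m, 2, n, "/")
  }
  S <- crossprod(nrm(reference), nrm(recovered))  # S[ref, rec] = cosine
  if (R <= 8) {
    perms <- permutations_all(R)
    scores <- vapply(seq_len(nrow(perms)),
                     function(i) sum(S[cbind(seq_len(R), perms[i, ])]),
                     numeric(1))
    perm <- perms[which.max(scores), ]
  } else {
    perm <- integer(R)
    free <- rep(TRUE, R)
    for (i in order(apply(S, 1, max), decreasing = TRUE)) {
      j <- which(free)[which.max(S[i, free])]
      perm[i] <- j; free[j] <- FALSE
    }
  }
  cos <- S[cbind(seq_len(R), perm)]
  list(perm = perm, cosines = cos, mean_cosine = mean(cos))
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}
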