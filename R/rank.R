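# Rank estimation for the tensor: NMF consensus clustering on a gene x sample
# slice, dispersion of the consensus matrix, elbow over a candidate grid.

#' Non-negative matrix factorization by multiplicative updates
#'
#' Frobenius-loss NMF `V ~ W H` with the classic multiplicative update rules,
#' used here only to probe clustering stability for rank estimation.
#'
#' @param V Non-negative matrix (features x samples).
#' @param rank Inner dimension r.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Update iterations.
#' @param eps Small constant guarding zero denominators.
#' @return List `W` (features x r), `H` (r x samples), `relative_error`.
#' @export
nmf_mu <- function(V, rank, seed = 1L, max_iter = 200L, eps = 1e-10) {
  if (any(V < 0)) stop("NMF input must be non-negative")
  if (rank >= ncol(V)) stop("NMF rank must be smaller than the number of samples")
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * rank), n, rank)
  H <- matrix(stats::runif(rank * m), rank, m)
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  nv <- frobenius(V)
  list(W = W, H = H,
       relative_error = if (nv > 0) frobenius(V - W %*% H) / nv else 0)
}

#' Dispersion of a consensus matrix
#'
#' `rho = (1/M^2) * sum_ij 4 (C_ij - 1/2)^2`: 1 for a perfectly stable
#' clustering (all entries 0 or 1), 0 for a maximally unstable one (all 0.5).
#'
#' @param C Square consensus matrix with entries in `[0,1]`.
#' @return Scalar in `[0,1]`.
#' @export
dispersion <- function(C) {
  stopifnot(nrow(C) == ncol(C))
  mean(4 * (C - 0.5)^2)
}

#' Consensus-clustering dispersion of an NMF rank
#'
#' Runs `n_runs` NMF factorizations from different seeded initializations,
#' assigns each sample to its maximum-coefficient basis column, accumulates
#' the M x M consensus matrix (fraction of runs co-clustering each sample
#' pair) and returns its dispersion.
#'
#' @param slice Non-negative gene x sample matrix.
#' @param rank NMF rank to probe (must be < number of samples).
#' @param n_runs Number of seeded NMF runs.
#' @param seed Base seed; run t uses `seed + t - 1`.
#' @param max_iter NMF iterations per run.
#' @return List `rho`, `consensus` (M x M), `rank`, `n_runs`.
#' @export
consensus_dispersion <- function(slice, rank, n_runs = 20L, seed = 1L,
                                 max_iter = 200L) {
  m <- ncol(slice)
  if (rank >= m) stop("rank must be smaller than the number of samples")
  consensus <- matrix(0, m, m)
  for (t in seq_len(n_runs)) {
    fit <- nmf_mu(slice, rank, seed = seed + t - 1L, max_iter = max_iter)
    cl <- max.col(t(fit$H), ties.method = "first")
    same <- outer(cl, cl, "==")
    consensus <- consensus + same
  }
  consensus <- consensus / n_runs
  list(rho = dispersion(consensus), consensus = consensus,
       rank = rank, n_runs = n_runs)
}

#' Scan candidate NMF ranks by consensus dispersion
#'
#' @param slice Non-negative gene x sample matrix.
#' @param ranks Candidate rank grid (increasing).
#' @param n_runs NMF runs per rank.
#' @param seed Base seed.
#' @param max_iter NMF iterations per run.
#' @return A `rank_scan`: data.frame `rank, rho` with attributes `n_runs` and
#'   `chosen` (filled by [choose_rank()]).
#' @export
rank_scan <- function(slice, ranks, n_runs = 20L, seed = 1L, max_iter = 200L) {
  ranks <- sort(unique(as.integer(ranks)))
  rho <- vapply(seq_along(ranks), function(i) {
    consensus_dispersion(slice, ranks[i], n_runs = n_runs,
                         seed = seed + 1000L * (i - 1L),
                         max_iter = max_iter)$rho
  }, numeric(1))
  structure(data.frame(rank = ranks, rho = rho),
            n_runs = n_runs, class = c("rank_scan", "data.frame"))
}

#' Pick a rank from a dispersion curve by the elbow rule
#'
#' The elbow is the candidate maximizing the second forward difference of the
#' dispersion curve, `rho[i+2] - 2*rho[i+1] + rho[i]` — the point after which
#' the stability drop flattens out. Ties resolve to the smaller rank; a curve
#' with no usable curvature (fewer than 3 candidates, or exactly linear)
#' falls back to the smallest candidate with a warning.
#'
#' @param scan `rank_scan` or data.frame with columns `rank`, `rho`.
#' @return Chosen rank (integer).
#' @export
choose_rank <- function(scan) {
  ranks <- scan$rank; rho <- scan$rho
  n <- length(ranks)
  if (n == 0) stop("empty rank scan")
  if (n == 1) return(ranks[1])
  if (n == 2) {
    warning("only two candidates: no curvature, returning the smaller rank")
    return(ranks[1])
  }
  d2 <- rho[seq_len(n - 2) + 2] - 2 * rho[seq_len(n - 2) + 1] + rho[seq_len(n - 2)]
  if (diff(range(d2)) < 1e-12) {
    warning("dispersion curve has no elbow (constant curvature); returning the smallest candidate")
    return(ranks[1])
  }
  ranks[which.max(d2)]  # which.max takes the first (smaller rank) on ties
}
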