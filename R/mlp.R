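# Minimal single-hidden-layer multilayer perceptron for the feature-scoring
# harness: ReLU hidden units, softmax output, cross-entropy loss, full-batch
# Adam, fully deterministic given the seed. Kept deliberately small — the
# classifier is a measuring instrument here, not the object of study.

#' Fit a single-hidden-layer MLP classifier
#'
#' @param X Numeric matrix (samples x features).
#' @param y Factor or character vector of class labels.
#' @param hidden Number of ReLU hidden units.
#' @param epochs Full-batch gradient steps.
#' @param lr Adam learning rate.
#' @param l2 L2 weight decay on the weights (not biases).
#' @param seed Integer seed for the He-style initialization.
#' @return An `mlp_fit` with weight matrices, class levels, and the
#'   standardization statistics used on the inputs.
#' @export
mlp_fit <- function(X, y, hidden = 100L, epochs = 500L, lr = 0.01,
                    l2 = 1e-4, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  lev <- levels(y)
  n <- nrow(X); p <- ncol(X); k <- length(lev)
  # standardize inputs (training statistics only)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), as.integer(y))] <- 1

  set.seed(seed %% .Machine$integer.max)
  W1 <- matrix(stats::rnorm(p * hidden, sd = sqrt(2 / max(p, 1))), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(stats::rnorm(hidden * k, sd = sqrt(2 / hidden)), hidden, k)
  b2 <- numeric(k)

  adam <- function() list(m = 0, v = 0)
  st <- list(W1 = adam(), b1 = adam(), W2 = adam(), b2 = adam())
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- function(state, grad, t) {
    state$m <- beta1 * state$m + (1 - beta1) * grad
    state$v <- beta2 * state$v + (1 - beta2) * grad^2
    mhat <- state$m / (1 - beta1^t)
    vhat <- state$v / (1 - beta2^t)
    list(state = state, delta = lr * mhat / (sqrt(vhat) + eps))
  }

  for (t in seq_len(epochs)) {
    H <- pmax(Xs %*% W1 + rep(b1, each = n), 0)            # n x hidden
    Z <- H %*% W2 + rep(b2, each = n)                      # n x k
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z); P <- P / rowSums(P)
    dZ <- (P - Y) / n
    gW2 <- crossprod(H, dZ) + l2 * W2
    gb2 <- colSums(dZ)
    dH <- dZ %*% t(W2) * (H > 0)
    gW1 <- crossprod(Xs, dH) + l2 * W1
    gb1 <- colSums(dH)
    s <- step(st$W1, gW1, t); st$W1 <- s$state; W1 <- W1 - s$delta
    s <- step(st$b1, gb1, t); st$b1 <- s$state; b1 <- b1 - s$delta
    s <- step(st$W2, gW2, t); st$W2 <- s$state; W2 <- W2 - s$delta
    s <- step(st$b2, gb2, t); st$b2 <- s$state; b2 <- b2 - s$delta
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, levels = lev,
                 mu = mu, sd = sdv),
            class = "mlp_fit")
}

#' Predict class labels from a fitted MLP
#'
#' @param object `mlp_fit`.
#' @param newdata Matrix (samples x features, same columns as training).
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.mlp_fit <- function(object, newdata, ...) {
  X <- sweep(sweep(as.matrix(newdata), 2, object$mu), 2, object$sd, "/")
  n <- nrow(X)
  H <- pmax(X %*% object$W1 + rep(object$b1, each = n), 0)
  Z <- H %*% object$W2 + rep(object$b2, each = n)
  factor(object$levels[max.col(Z, ties.method = "first")],
         levels = object$levels)
}
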