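# Compact multilayer perceptron written in base R matrix operations: two ReLU
# hidden layers, softmax (classification) or linear (regression) output, Adam
# updates, L2 penalty, minibatches, and early stopping on an inner 10% split.
# Desk-scale by design: inputs are ~1k-bit fingerprints and training sets a
# few thousand rows.

relu <- function(x) (x + abs(x)) / 2

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

adam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^t)
    vh <- state$v[[nm]] / (1 - beta2^t)
    state$par[[nm]] <- state$par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  state
}

init_mlp <- function(p, hidden, k_out) {
  dims <- c(p, hidden, k_out)
  par <- list()
  for (l in seq_len(length(dims) - 1L)) {
    par[[paste0("W", l)]] <- matrix(
      stats::rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
      dims[l], dims[l + 1])
    par[[paste0("b", l)]] <- rep(0, dims[l + 1])
  }
  par
}

mlp_forward <- function(par, X) {
  A1 <- relu(sweep(X %*% par$W1, 2, par$b1, "+"))
  A2 <- relu(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  Z3 <- sweep(A2 %*% par$W3, 2, par$b3, "+")
  list(A1 = A1, A2 = A2, Z3 = Z3)
}

mlp_loss <- function(par, X, Y, w, task, alpha) {
  fw <- mlp_forward(par, X)
  if (task == "classification") {
    P <- softmax_rows(fw$Z3)
    data_loss <- -sum(w * log(pmax(rowSums(P * Y), 1e-12))) / sum(w)
  } else {
    data_loss <- sum(w * (fw$Z3[, 1] - Y)^2) / sum(w)
  }
  data_loss + alpha * (sum(par$W1^2) + sum(par$W2^2) + sum(par$W3^2))
}

mlp_grads <- function(par, X, Y, w, task, alpha) {
  fw <- mlp_forward(par, X)
  sw <- sum(w)
  if (task == "classification") {
    P <- softmax_rows(fw$Z3)
    dZ3 <- (P - Y) * (w / sw)
  } else {
    dZ3 <- matrix(2 * w * (fw$Z3[, 1] - Y) / sw, ncol = 1)
  }
  dW3 <- crossprod(fw$A2, dZ3) + 2 * alpha * par$W3
  db3 <- colSums(dZ3)
  dA2 <- tcrossprod(dZ3, par$W3) * (fw$A2 > 0)
  dW2 <- crossprod(fw$A1, dA2) + 2 * alpha * par$W2
  db2 <- colSums(dA2)
  dA1 <- tcrossprod(dA2, par$W2) * (fw$A1 > 0)
  dW1 <- crossprod(X, dA1) + 2 * alpha * par$W1
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

#' Fit a two-hidden-layer perceptron
#'
#' @param X Numeric feature matrix (fingerprint bits + standardized physchem).
#' @param y Factor (classification) or numeric (regression).
#' @param task `"classification"` or `"regression"`.
#' @param hidden Integer 2-vector of hidden layer sizes, e.g. `c(512, 128)`.
#' @param alpha L2 penalty.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without inner-split
#'   improvement); the inner split holds out 10% of the rows.
#' @param weights Optional per-sample weights.
#' @param seed RNG seed (initialization, shuffling, inner split).
#' @return A list of class `mlp_fit`.
#' @keywords internal
mlp_fit <- function(X, y, task = c("classification", "regression"),
                    hidden = c(256, 64), alpha = 1e-4, lr = 1e-3,
                    batch_size = 128, epochs = 60, patience = 8,
                    weights = NULL, seed = 1) {
  task <- match.arg(task)
  set.seed(seed)
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  if (task == "classification") {
    yf <- factor(y)
    classes <- levels(yf)
    Y <- diag(length(classes))[as.integer(yf), , drop = FALSE]
    k_out <- length(classes)
  } else {
    classes <- NULL
    Y <- as.numeric(y)
    k_out <- 1L
  }
  hold <- sample(n, max(1L, round(0.1 * n)))
  tr <- setdiff(seq_len(n), hold)
  par <- init_mlp(ncol(X), hidden, k_out)
  state <- list(par = par,
                m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))
  best <- list(loss = Inf, par = par)
  stall <- 0L; t <- 0L
  Yv <- if (is.matrix(Y)) Y[hold, , drop = FALSE] else Y[hold]
  Yt <- if (is.matrix(Y)) Y[tr, , drop = FALSE] else Y[tr]
  for (ep in seq_len(epochs)) {
    idx <- sample(tr)
    for (start in seq(1, length(idx), by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1L, length(idx))]
      Yb <- if (is.matrix(Y)) Y[b, , drop = FALSE] else Y[b]
      g <- mlp_grads(state$par, X[b, , drop = FALSE], Yb, weights[b],
                     task, alpha)
      t <- t + 1L
      state <- adam_step(state, g, lr, t)
    }
    vloss <- mlp_loss(state$par, X[hold, , drop = FALSE], Yv, weights[hold],
                      task, alpha)
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, par = state$par); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(par = best$par, task = task, classes = classes,
                 hidden = hidden),
            class = "mlp_fit")
}

#' @keywords internal
mlp_predict <- function(fit, X) {
  fw <- mlp_forward(fit$par, X)
  if (fit$task == "classification") {
    P <- softmax_rows(fw$Z3)
    colnames(P) <- fit$classes
    P
  } else {
    fw$Z3[, 1]
  }
}
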