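# Minimal graph convolutional network in base R: two symmetric-normalized
# graph-convolution layers of equal hidden dimension with ReLU and dropout,
# mean-pooling readout, physicochemical 4-vector concatenated at the readout,
# and a linear head. Trained with Adam; molecules are processed per-graph
# (volatiles are small molecules, so dense per-molecule algebra is cheap).

gcn_node_features <- function(graph, vocab) {
  el <- graph$atoms$element
  onehot <- matrix(0, length(el), length(vocab))
  hit <- match(el, vocab)                 # unseen elements get an all-zero row
  ok <- !is.na(hit)
  onehot[cbind(which(ok), hit[ok])] <- 1
  cbind(onehot, degree = graph$atoms$degree / 4,
        aromatic = as.numeric(graph$atoms$aromatic))
}

gcn_norm_adj <- function(graph) {
  n <- nrow(graph$atoms)
  A <- diag(n)
  if (nrow(graph$bonds)) {
    A[cbind(graph$bonds$i, graph$bonds$j)] <- 1
    A[cbind(graph$bonds$j, graph$bonds$i)] <- 1
  }
  dinv <- 1 / sqrt(rowSums(A))
  A * tcrossprod(dinv)
}

#' Fit a graph convolutional network
#'
#' @param graphs List of [to_graph()] objects.
#' @param y Factor (classification) or numeric (regression).
#' @param task `"classification"` or `"regression"`.
#' @param hidden Hidden dimension of both graph-convolution layers.
#' @param dropout Dropout rate on hidden activations during training.
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty on the weight matrices.
#' @param batch_size Molecules per gradient step.
#' @param epochs,patience Training length and early stopping (inner 10% split).
#' @param weights Optional per-sample weights.
#' @param seed RNG seed.
#' @return A list of class `gcn_fit`.
#' @keywords internal
gcn_fit <- function(graphs, y, task = c("classification", "regression"),
                    hidden = 64, dropout = 0.1, lr = 1e-3, weight_decay = 0,
                    batch_size = 64, epochs = 40, patience = 6,
                    weights = NULL, seed = 1) {
  task <- match.arg(task)
  set.seed(seed)
  n <- length(graphs)
  if (is.null(weights)) weights <- rep(1, n)
  vocab <- sort(unique(unlist(lapply(graphs, function(g) g$atoms$element))))
  pmat <- do.call(rbind, lapply(graphs, function(g) g$physchem))
  pc_mean <- colMeans(pmat); pc_sd <- pmax(apply(pmat, 2, stats::sd), 1e-8)
  pstd <- sweep(sweep(pmat, 2, pc_mean), 2, pc_sd, "/")
  pre <- lapply(graphs, function(g)
    list(X = gcn_node_features(g, vocab), A = gcn_norm_adj(g)))

  if (task == "classification") {
    yf <- factor(y); classes <- levels(yf)
    Y <- diag(length(classes))[as.integer(yf), , drop = FALSE]
    k_out <- length(classes)
  } else {
    classes <- NULL; Y <- as.numeric(y); k_out <- 1L
  }
  d_in <- ncol(pre[[1]]$X)
  par <- list(
    W1 = matrix(stats::rnorm(d_in * hidden, sd = sqrt(2 / d_in)), d_in, hidden),
    W2 = matrix(stats::rnorm(hidden * hidden, sd = sqrt(2 / hidden)), hidden, hidden),
    W3 = matrix(stats::rnorm((hidden + 4) * k_out, sd = sqrt(2 / (hidden + 4))),
                hidden + 4, k_out),
    b3 = rep(0, k_out))
  state <- list(par = par, m = lapply(par, function(p) p * 0),
                v = lapply(par, function(p) p * 0))

  fwd <- function(par, i, drop_masks = NULL) {
    X <- pre[[i]]$X; A <- pre[[i]]$A
    AX <- A %*% X
    H1 <- relu(AX %*% par$W1)
    H1d <- if (is.null(drop_masks)) H1 else H1 * drop_masks$m1 / (1 - dropout)
    AH <- A %*% H1d
    H2 <- relu(AH %*% par$W2)
    H2d <- if (is.null(drop_masks)) H2 else H2 * drop_masks$m2 / (1 - dropout)
    r <- colMeans(H2d)
    z <- c(r, pstd[i, ])
    list(AX = AX, H1 = H1, H1d = H1d, AH = AH, H2 = H2, H2d = H2d, z = z,
         out = drop(z %*% par$W3) + par$b3)
  }
  out_loss <- function(out, i) {
    if (task == "classification") {
      p <- exp(out - max(out)); p <- p / sum(p)
      -weights[i] * log(max(p[which(Y[i, ] == 1)], 1e-12))
    } else {
      weights[i] * (out[1] - Y[i])^2
    }
  }
  dout_fn <- function(out, i) {
    if (task == "classification") {
      p <- exp(out - max(out)); p <- p / sum(p)
      weights[i] * (p - Y[i, ])
    } else {
      weights[i] * 2 * (out[1] - Y[i])
    }
  }

  hold <- sample(n, max(1L, round(0.1 * n)))
  tr <- setdiff(seq_len(n), hold)
  val_loss <- function(par)
    sum(vapply(hold, function(i) out_loss(fwd(par, i)$out, i), 0)) /
      sum(weights[hold])
  best <- list(loss = Inf, par = par); stall <- 0L; t <- 0L
  for (ep in seq_len(epochs)) {
    idx <- sample(tr)
    for (start in seq(1, length(idx), by = batch_size)) {
      b <- idx[start:min(start + batch_size - 1L, length(idx))]
      g <- lapply(state$par, function(p) p * 0)
      for (i in b) {
        msk <- if (dropout > 0)
          list(m1 = matrix(stats::rbinom(nrow(pre[[i]]$X) * hidden, 1, 1 - dropout),
                           ncol = hidden),
               m2 = matrix(stats::rbinom(nrow(pre[[i]]$X) * hidden, 1, 1 - dropout),
                           ncol = hidden))
        else NULL
        f <- fwd(state$par, i, msk)
        dout <- dout_fn(f$out, i)
        g$W3 <- g$W3 + outer(f$z, dout)
        g$b3 <- g$b3 + dout
        dz <- drop(state$par$W3 %*% dout)
        dr <- dz[seq_len(hidden)]
        ni <- nrow(pre[[i]]$X)
        dH2d <- matrix(dr / ni, ni, hidden, byrow = TRUE)
        dH2 <- if (is.null(msk)) dH2d else dH2d * msk$m2 / (1 - dropout)
        dpre2 <- dH2 * (f$H2 > 0)
        g$W2 <- g$W2 + crossprod(f$AH, dpre2)
        dH1d <- pre[[i]]$A %*% tcrossprod(dpre2, state$par$W2)
        dH1 <- if (is.null(msk)) dH1d else dH1d * msk$m1 / (1 - dropout)
        dpre1 <- dH1 * (f$H1 > 0)
        g$W1 <- g$W1 + crossprod(f$AX, dpre1)
      }
      sw <- sum(weights[b])
      for (nm in c("W1", "W2", "W3")) {
        g[[nm]] <- g[[nm]] / sw + 2 * weight_decay * state$par[[nm]]
      }
      g$b3 <- g$b3 / sw
      t <- t + 1L
      state <- adam_step(state, g, lr, t)
    }
    vl <- val_loss(state$par)
    if (vl < best$loss - 1e-6) {
      best <- list(loss = vl, par = state$par); stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  structure(list(par = best$par, task = task, classes = classes,
                 vocab = vocab, hidden = hidden, dropout = dropout,
                 pc_mean = pc_mean, pc_sd = pc_sd),
            class = "gcn_fit")
}

#' @keywords internal
gcn_predict <- function(fit, graphs) {
  one <- function(g) {
    X <- gcn_node_features(g, fit$vocab)
    A <- gcn_norm_adj(g)
    H1 <- relu(A %*% X %*% fit$par$W1)
    H2 <- relu(A %*% H1 %*% fit$par$W2)
    z <- c(colMeans(H2), (g$physchem - fit$pc_mean) / fit$pc_sd)
    drop(z %*% fit$par$W3) + fit$par$b3
  }
  outs <- do.call(rbind, lapply(graphs, one))
  if (fit$task == "classification") {
    P <- softmax_rows(outs)
    colnames(P) <- fit$classes
    P
  } else {
    outs[, 1]
  }
}
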