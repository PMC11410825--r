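# Improved recurrent network: a single-cell LSTM fed the pair feature vector
# as a length-T sequence of scalars, followed by a three-layer dense head
# (tanh, tanh, logistic) emitting an interaction score in (0,1).
#
# Gates (logistic theta, tanh candidate):
#   F_t = theta(W_F [H_{t-1}, x_t] + d_F)      forget
#   i_t = theta(W_i [H_{t-1}, x_t] + d_i)      input
#   e~_t = tanh(W_e [H_{t-1}, x_t] + d_e)      candidate
#   q_t = theta(W_q [H_{t-1}, x_t] + b_q)      output
#   e_t = F_t * e_{t-1} + i_t * e~_t           cell state
#   H_t = q_t * tanh(e_t)
# Training minimizes the mean binary cross-entropy by stochastic gradient
# descent with momentum (sgdm), gradients computed by backpropagation
# through time.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize LSTM parameters
#'
#' Gate and head weights drawn at the Glorot scale (standard deviation
#' `1/sqrt(fan_in)`) so activations have usable spread from the first
#' iteration; biases start at zero except the forget-gate bias, which starts
#' at 1 to keep early cell states alive.
#'
#' @param hidden Hidden state size.
#' @param head_sizes Sizes of the two hidden dense layers of the head.
#' @param init_scale Multiplier on the Glorot scale (default 1).
#' @return An `lstm_params` list of gate and head weights.
#' @export
init_lstm_params <- function(hidden = 8L, head_sizes = c(16L, 8L),
                             init_scale = 1) {
  h <- as.integer(hidden)
  gw <- function() matrix(stats::rnorm(h * (h + 1), sd = init_scale / sqrt(h + 1)),
                          h, h + 1)
  dense <- function(nout, nin) {
    matrix(stats::rnorm(nout * nin, sd = init_scale / sqrt(nin)), nout, nin)
  }
  n1 <- head_sizes[1]; n2 <- head_sizes[2]
  structure(list(
    h = h,
    Wf = gw(), df = rep(1, h),
    Wi = gw(), di = rep(0, h),
    We = gw(), de = rep(0, h),
    Wq = gw(), bq = rep(0, h),
    W1 = dense(n1, h), b1 = rep(0, n1),
    W2 = dense(n2, n1), b2 = rep(0, n2),
    W3 = dense(1L, n2), b3 = 0
  ), class = "lstm_params")
}

# batched forward pass; X is N x T, each row a feature vector presented as a
# sequence of scalars. Returns scores and, optionally, the per-step cache
# needed for backpropagation.
lstm_forward_batch <- function(params, X, keep_cache = FALSE) {
  p <- params
  h <- p$h
  N <- nrow(X); TT <- ncol(X)
  H <- matrix(0, h, N)
  C <- matrix(0, h, N)
  cache <- if (keep_cache) vector("list", TT) else NULL
  for (t in seq_len(TT)) {
    Z <- rbind(H, X[, t])
    Fg <- sigmoid(p$Wf %*% Z + p$df)
    Ig <- sigmoid(p$Wi %*% Z + p$di)
    Eg <- tanh(p$We %*% Z + p$de)
    Qg <- sigmoid(p$Wq %*% Z + p$bq)
    Cprev <- C
    C <- Fg * Cprev + Ig * Eg
    tC <- tanh(C)
    H <- Qg * tC
    if (keep_cache) cache[[t]] <- list(Z = Z, F = Fg, I = Ig, E = Eg, Q = Qg,
                                       Cprev = Cprev, tC = tC)
    if (any(!is.finite(H))) stop2("non-finite LSTM activation at step ", t)
  }
  A1 <- tanh(p$W1 %*% H + p$b1)
  A2 <- tanh(p$W2 %*% A1 + p$b2)
  S <- sigmoid(p$W3 %*% A2 + p$b3)
  list(scores = as.vector(S), H = H, A1 = A1, A2 = A2, cache = cache)
}

#' LSTM forward pass for one feature vector
#'
#' @param params An `lstm_params` list.
#' @param feature_sequence Numeric vector presented to the cell one scalar
#'   per time step.
#' @return Interaction score in (0, 1).
#' @export
lstm_forward <- function(params, feature_sequence) {
  lstm_forward_batch(params, matrix(feature_sequence, nrow = 1L))$scores
}

#' Predict scores for a feature matrix
#'
#' @param params An `lstm_params` list.
#' @param X Numeric matrix, one row per pair.
#' @return Numeric vector of scores in (0, 1).
#' @export
mrnn_predict <- function(params, X) {
  lstm_forward_batch(params, as.matrix(X))$scores
}

#' Mean binary cross-entropy loss
#'
#' `-mean(z * log(s) + (1 - z) * log(1 - s))` with scores clipped to
#' `[eps, 1 - eps]`.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted scores.
#' @param eps Clipping floor (default 1e-12).
#' @return Non-negative scalar.
#' @examples
#' cross_entropy(1, 0.5)  # -log(0.5) = 0.6931...
#' @export
cross_entropy <- function(labels, scores, eps = 1e-12) {
  if (length(labels) != length(scores)) stop2("labels/scores length mismatch")
  if (!all(labels %in% c(0, 1))) stop2("labels must be 0/1")
  s <- clamp(scores, eps, 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

# loss and analytic gradients for one batch; returns list(loss, grads) where
# grads mirrors the parameter list structure.
lstm_loss_grad <- function(params, X, y) {
  p <- params
  h <- p$h
  X <- as.matrix(X)
  N <- nrow(X); TT <- ncol(X)
  fw <- lstm_forward_batch(p, X, keep_cache = TRUE)
  s <- clamp(fw$scores, 1e-12, 1 - 1e-12)
  loss <- -mean(y * log(s) + (1 - y) * log(1 - s))

  g <- list(Wf = 0 * p$Wf, df = 0 * p$df, Wi = 0 * p$Wi, di = 0 * p$di,
            We = 0 * p$We, de = 0 * p$de, Wq = 0 * p$Wq, bq = 0 * p$bq,
            W1 = 0 * p$W1, b1 = 0 * p$b1, W2 = 0 * p$W2, b2 = 0 * p$b2,
            W3 = 0 * p$W3, b3 = 0)
  # head backward: d(loss)/d(z3) = (s - y)/N for the logistic output
  dz3 <- matrix((s - y) / N, 1, N)
  g$W3 <- dz3 %*% t(fw$A2)
  g$b3 <- sum(dz3)
  dA2 <- t(p$W3) %*% dz3
  dz2 <- dA2 * (1 - fw$A2^2)
  g$W2 <- dz2 %*% t(fw$A1)
  g$b2 <- rowSums(dz2)
  dA1 <- t(p$W2) %*% dz2
  dz1 <- dA1 * (1 - fw$A1^2)
  g$W1 <- dz1 %*% t(fw$H)
  g$b1 <- rowSums(dz1)
  dH <- t(p$W1) %*% dz1

  dC <- matrix(0, h, N)
  for (t in rev(seq_len(TT))) {
    cc <- fw$cache[[t]]
    dQ <- dH * cc$tC
    dC <- dC + dH * cc$Q * (1 - cc$tC^2)
    dF <- dC * cc$Cprev
    dI <- dC * cc$E
    dE <- dC * cc$I
    dCprev <- dC * cc$F
    dzF <- dF * cc$F * (1 - cc$F)
    dzI <- dI * cc$I * (1 - cc$I)
    dzE <- dE * (1 - cc$E^2)
    dzQ <- dQ * cc$Q * (1 - cc$Q)
    tZ <- t(cc$Z)
    g$Wf <- g$Wf + dzF %*% tZ; g$df <- g$df + rowSums(dzF)
    g$Wi <- g$Wi + dzI %*% tZ; g$di <- g$di + rowSums(dzI)
    g$We <- g$We + dzE %*% tZ; g$de <- g$de + rowSums(dzE)
    g$Wq <- g$Wq + dzQ %*% tZ; g$bq <- g$bq + rowSums(dzQ)
    dZ <- t(p$Wf) %*% dzF + t(p$Wi) %*% dzI + t(p$We) %*% dzE + t(p$Wq) %*% dzQ
    dH <- dZ[seq_len(h), , drop = FALSE]
    dC <- dCprev
  }
  list(loss = loss, grads = g)
}

#' Train the improved recurrent network
#'
#' Stochastic gradient descent with momentum on the mean cross-entropy loss.
#' Each epoch shuffles the training pairs into mini-batches; the loss trace
#' records the full-data loss before training (epoch 0) and after every
#' epoch. Training is deterministic given the seed.
#'
#' @param X Numeric matrix of pair features in \[0, 1\], one row per pair.
#' @param y 0/1 labels.
#' @param config List of hyperparameters; defaults: `hidden = 8`,
#'   `head_sizes = c(16, 8)`, `lr = 0.01`, `momentum = 0.9`, `epochs = 50`,
#'   `batch = 70`, `seed = 1`.
#' @return List with `params` (trained `lstm_params`), `trace` (numeric
#'   vector of length `epochs + 1`) and `scores` on the training data.
#' @export
train_mrnn <- function(X, y, config = list()) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < 1L) stop2("need at least one training example")
  cfg <- utils::modifyList(list(hidden = 8L, head_sizes = c(16L, 8L),
                                lr = 0.01, momentum = 0.9, epochs = 50L,
                                batch = 70L, seed = 1L, init_scale = 1),
                           config)
  set.seed(cfg$seed)
  params <- init_lstm_params(cfg$hidden, cfg$head_sizes, cfg$init_scale)
  vel <- lapply(params[-1], function(w) 0 * w)  # skip the size slot `h`
  pnames <- names(vel)
  trace <- numeric(cfg$epochs + 1L)
  trace[1] <- cross_entropy(y, mrnn_predict(params, X))
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    starts <- seq(1L, N, by = cfg$batch)
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + cfg$batch - 1L, N)]
      lg <- lstm_loss_grad(params, X[idx, , drop = FALSE], y[idx])
      if (!is.finite(lg$loss)) stop2("training diverged at epoch ", epoch)
      for (nm in pnames) {
        vel[[nm]] <- cfg$momentum * vel[[nm]] - cfg$lr * lg$grads[[nm]]
        params[[nm]] <- params[[nm]] + vel[[nm]]
      }
    }
    trace[epoch + 1L] <- cross_entropy(y, mrnn_predict(params, X))
    if (!is.finite(trace[epoch + 1L])) stop2("training diverged at epoch ", epoch)
  }
  list(params = params, trace = trace, scores = mrnn_predict(params, X))
}
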