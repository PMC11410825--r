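# Deep belief network: stacked restricted Boltzmann machines pre-trained
# greedily with one-step contrastive divergence (CD-1), then the whole stack
# plus a logistic output head fine-tuned by gradient descent on the
# cross-entropy loss.
#
# RBM energy for visible v (length p) and hidden h (length q):
#   E(v, h) = -sum_r A_r v_r - sum_j B_j h_j - sum_rj v_r U_rj h_j
# with conditionals P(h_j = 1 | v) = sigma(B_j + sum_r v_r U_rj) and
# P(v_r = 1 | h) = sigma(A_r + sum_j U_rj h_j).

#' Initialize RBM parameters
#'
#' @param p Number of visible units.
#' @param q Number of hidden units.
#' @param init_scale Standard deviation of the initial weights; `NULL`
#'   (default) uses the fan-in scale `1/sqrt(p)`.
#' @return An `rbm_params` list with weight matrix `U` (p x q), visible bias
#'   `A` and hidden bias `B`.
#' @export
init_rbm_params <- function(p, q, init_scale = NULL) {
  if (is.null(init_scale)) init_scale <- 1 / sqrt(p)
  structure(list(U = matrix(stats::rnorm(p * q, sd = init_scale), p, q),
                 A = rep(0, p), B = rep(0, q)),
            class = "rbm_params")
}

#' RBM energy of a joint configuration
#'
#' @param params An `rbm_params` list.
#' @param v Visible vector (length p).
#' @param h Hidden vector (length q).
#' @return Scalar energy.
#' @examples
#' prm <- list(U = matrix(1), A = 0.5, B = 0.25)
#' rbm_energy(prm, 1, 1)  # -1.75
#' @export
rbm_energy <- function(params, v, h) {
  if (length(v) != nrow(params$U) || length(h) != ncol(params$U)) {
    stop2("v/h shapes do not match the weight matrix")
  }
  -sum(params$A * v) - sum(params$B * h) - as.numeric(v %*% params$U %*% h)
}

#' Hidden-unit activation probabilities given visible data
#'
#' @param params An `rbm_params` list.
#' @param V Matrix of visible vectors, one row each (or a single vector).
#' @return Matrix of `P(h_j = 1 | v)`, one row per input row.
#' @export
rbm_prob_h_given_v <- function(params, V) {
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  sigmoid(sweep(V %*% params$U, 2L, params$B, "+"))
}

#' Visible-unit activation probabilities given hidden states
#'
#' @param params An `rbm_params` list.
#' @param H Matrix of hidden vectors, one row each (or a single vector).
#' @return Matrix of `P(v_r = 1 | h)`, one row per input row.
#' @export
rbm_prob_v_given_h <- function(params, H) {
  if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
  sigmoid(sweep(H %*% t(params$U), 2L, params$A, "+"))
}

#' One CD-1 training epoch over a data set
#'
#' Runs one pass of one-step contrastive divergence over mini-batches:
#' sample hidden states given the data, reconstruct visible probabilities,
#' recompute hidden probabilities, and update with the positive-minus-negative
#' association gradient. Momentum and an L2 weight cost (weights only) are
#' applied.
#'
#' @param params An `rbm_params` list.
#' @param data Matrix of visible vectors in \[0, 1\], one row each.
#' @param lr Learning rate.
#' @param momentum Momentum coefficient for this epoch.
#' @param weight_cost L2 penalty on the weights.
#' @param batch Mini-batch size.
#' @param vel Velocity state from the previous epoch (`NULL` to start).
#' @return List with updated `params`, `vel` and the mean squared
#'   reconstruction error of the epoch.
#' @export
cd1_epoch <- function(params, data, lr = 0.01, momentum = 0.5,
                      weight_cost = 0.0002, batch = 200L, vel = NULL) {
  data <- as.matrix(data)
  N <- nrow(data)
  if (N == 0L) stop2("empty batch")
  if (is.null(vel)) vel <- list(U = 0 * params$U, A = 0 * params$A, B = 0 * params$B)
  starts <- seq(1L, N, by = batch)
  err <- 0
  for (s0 in starts) {
    V0 <- data[s0:min(s0 + batch - 1L, N), , drop = FALSE]
    n <- nrow(V0)
    Ph0 <- rbm_prob_h_given_v(params, V0)
    H0 <- (matrix(stats::runif(length(Ph0)), nrow(Ph0)) < Ph0) * 1
    V1 <- rbm_prob_v_given_h(params, H0)
    Ph1 <- rbm_prob_h_given_v(params, V1)
    dU <- (t(V0) %*% Ph0 - t(V1) %*% Ph1) / n - weight_cost * params$U
    dA <- colMeans(V0) - colMeans(V1)
    dB <- colMeans(Ph0) - colMeans(Ph1)
    vel$U <- momentum * vel$U + lr * dU
    vel$A <- momentum * vel$A + lr * dA
    vel$B <- momentum * vel$B + lr * dB
    params$U <- params$U + vel$U
    params$A <- params$A + vel$A
    params$B <- params$B + vel$B
    err <- err + sum((V0 - V1)^2)
  }
  list(params = params, vel = vel, recon_error = err / (N * ncol(data)))
}

#' Pre-train one RBM with CD-1
#'
#' @param data Matrix of visible vectors in \[0, 1\].
#' @param n_hidden Number of hidden units.
#' @param epochs Training epochs.
#' @param lr Learning rate.
#' @param batch Mini-batch size.
#' @param momentum_initial,momentum_final Momentum before/after
#'   `momentum_switch` epochs.
#' @param momentum_switch Epoch after which the final momentum applies.
#' @param weight_cost L2 penalty on the weights.
#' @return List with `params` and the per-epoch `recon_trace`.
#' @export
train_rbm <- function(data, n_hidden = 50L, epochs = 50L, lr = 0.01,
                      batch = 200L, momentum_initial = 0.5,
                      momentum_final = 0.9, momentum_switch = 5L,
                      weight_cost = 0.0002) {
  data <- as.matrix(data)
  params <- init_rbm_params(ncol(data), n_hidden)
  vel <- NULL
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    mom <- if (ep <= momentum_switch) momentum_initial else momentum_final
    step <- cd1_epoch(params, data, lr, mom, weight_cost, batch, vel)
    params <- step$params
    vel <- step$vel
    trace[ep] <- step$recon_error
    if (any(!is.finite(params$U))) stop2("RBM weights diverged at epoch ", ep)
  }
  list(params = params, recon_trace = trace)
}

dbn_hidden_forward <- function(rbms, X) {
  A <- X
  acts <- vector("list", length(rbms))
  for (i in seq_along(rbms)) {
    A <- rbm_prob_h_given_v(rbms[[i]], A)
    acts[[i]] <- A
  }
  list(top = A, acts = acts)
}

#' Predict interaction scores with a trained DBN
#'
#' @param model A `dbn_model` from [train_dbn_predict].
#' @param X Feature matrix in \[0, 1\], one row per pair.
#' @return Numeric vector of scores in (0, 1).
#' @export
dbn_predict <- function(model, X) {
  top <- dbn_hidden_forward(model$rbms, as.matrix(X))$top
  as.vector(sigmoid(top %*% model$w_out + model$b_out))
}

#' Train a DBN classifier
#'
#' Greedy layer-wise pre-training of the RBM stack with CD-1, then
#' fine-tuning of the whole stack plus a logistic output head by full-batch
#' gradient descent with momentum (same 0.5 to 0.9 schedule as
#' pre-training) on the mean cross-entropy loss. Inputs must be scaled to
#' \[0, 1\] (min-max normalization); values outside are an error.
#'
#' @param X Feature matrix in \[0, 1\], one row per pair.
#' @param y 0/1 labels.
#' @param config List of hyperparameters; defaults: `hidden = 50` (one RBM
#'   layer; a vector gives a deeper stack), `pretrain_epochs = 50`,
#'   `finetune_epochs = 100`, `lr = 0.01`, `batch = 200`,
#'   `momentum_initial = 0.5`, `momentum_final = 0.9`,
#'   `momentum_switch = 5`, `weight_cost = 0.0002`, `seed = 1`.
#' @return A `dbn_model`: list with `rbms`, output head weights, pre-training
#'   and fine-tuning loss traces, and `scores` on the training data.
#' @export
train_dbn_predict <- function(X, y, config = list()) {
  X <- as.matrix(X)
  if (any(X < 0 | X > 1)) stop2("DBN input must be scaled to [0, 1]")
  cfg <- utils::modifyList(list(hidden = 50L, pretrain_epochs = 50L,
                                finetune_epochs = 100L, lr = 0.01,
                                batch = 200L, momentum_initial = 0.5,
                                momentum_final = 0.9, momentum_switch = 5L,
                                weight_cost = 0.0002, seed = 1L),
                           config)
  set.seed(cfg$seed)
  rbms <- list()
  layer_in <- X
  pretrain_traces <- list()
  for (i in seq_along(cfg$hidden)) {
    fit <- train_rbm(layer_in, n_hidden = cfg$hidden[i],
                     epochs = cfg$pretrain_epochs, lr = cfg$lr,
                     batch = cfg$batch,
                     momentum_initial = cfg$momentum_initial,
                     momentum_final = cfg$momentum_final,
                     momentum_switch = cfg$momentum_switch,
                     weight_cost = cfg$weight_cost)
    rbms[[i]] <- fit$params
    pretrain_traces[[i]] <- fit$recon_trace
    layer_in <- rbm_prob_h_given_v(fit$params, layer_in)
  }
  q_top <- cfg$hidden[length(cfg$hidden)]
  w_out <- stats::rnorm(q_top, sd = 1 / sqrt(q_top))
  b_out <- 0

  finetune_trace <- numeric(cfg$finetune_epochs + 1L)
  forward_all <- function() {
    fwd <- dbn_hidden_forward(rbms, X)
    s <- as.vector(sigmoid(fwd$top %*% w_out + b_out))
    list(fwd = fwd, s = s)
  }
  st <- forward_all()
  finetune_trace[1] <- cross_entropy(y, st$s)
  N <- nrow(X)
  vel_w <- 0 * w_out; vel_b <- 0
  vel_rbm <- lapply(rbms, function(r) list(U = 0 * r$U, B = 0 * r$B))
  for (ep in seq_len(cfg$finetune_epochs)) {
    mom <- if (ep <= cfg$momentum_switch) cfg$momentum_initial else cfg$momentum_final
    fwd <- st$fwd
    s <- st$s
    dz <- (s - y) / N                       # gradient at the logistic output
    gw <- as.vector(t(fwd$top) %*% dz)
    gb <- sum(dz)
    dtop <- outer(dz, w_out)                # N x q_top
    # back through the sigmoid stack
    dact <- dtop
    grads <- vector("list", length(rbms))
    for (i in rev(seq_along(rbms))) {
      act <- fwd$acts[[i]]
      dpre <- dact * act * (1 - act)
      below <- if (i == 1L) X else fwd$acts[[i - 1L]]
      grads[[i]] <- list(U = t(below) %*% dpre, B = colSums(dpre))
      dact <- dpre %*% t(rbms[[i]]$U)
    }
    vel_w <- mom * vel_w - cfg$lr * gw
    vel_b <- mom * vel_b - cfg$lr * gb
    w_out <- w_out + vel_w
    b_out <- b_out + vel_b
    for (i in seq_along(rbms)) {
      vel_rbm[[i]]$U <- mom * vel_rbm[[i]]$U - cfg$lr * grads[[i]]$U
      vel_rbm[[i]]$B <- mom * vel_rbm[[i]]$B - cfg$lr * grads[[i]]$B
      rbms[[i]]$U <- rbms[[i]]$U + vel_rbm[[i]]$U
      rbms[[i]]$B <- rbms[[i]]$B + vel_rbm[[i]]$B
    }
    st <- forward_all()
    finetune_trace[ep + 1L] <- cross_entropy(y, st$s)
    if (!is.finite(finetune_trace[ep + 1L])) stop2("fine-tuning diverged at epoch ", ep)
  }
  structure(list(rbms = rbms, w_out = w_out, b_out = b_out,
                 pretrain_traces = pretrain_traces,
                 finetune_trace = finetune_trace,
                 scores = st$s),
            class = "dbn_model")
}
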