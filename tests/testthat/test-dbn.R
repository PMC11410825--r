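# Restricted Boltzmann machine and deep belief network.

test_that("RBM energy matches the three-term hand sum", {
  prm <- list(U = matrix(1), A = 0.5, B = 0.25)
  expect_equal(rbm_energy(prm, 0, 0), 0)
  expect_equal(rbm_energy(prm, 1, 1), -1.75)  # -(0.5 + 0.25 + 1)
  expect_error(rbm_energy(prm, c(1, 0), 1), "shapes")
})

test_that("RBM energy is linear in each bias vector", {
  set.seed(21)
  prm <- init_rbm_params(4, 3)
  v <- rbinom(4, 1, 0.5); h <- rbinom(3, 1, 0.5)
  e0 <- rbm_energy(prm, v, h)
  prm2 <- prm; prm2$A <- prm$A + c(1, 0, 0, 0)
  expect_equal(rbm_energy(prm2, v, h), e0 - v[1])
  prm3 <- prm; prm3$B <- prm$B * 2
  expect_equal(rbm_energy(prm3, v, h), e0 - sum(prm$B * h))
})

test_that("conditional activation probabilities follow the logistic form", {
  prm <- init_rbm_params(3, 2, init_scale = 0)
  expect_equal(unname(rbm_prob_h_given_v(prm, c(1, 0, 1))[1, ]), c(0.5, 0.5))
  expect_equal(unname(rbm_prob_v_given_h(prm, c(1, 1))[1, ]), rep(0.5, 3))
  # monotone in the bias
  prm$B <- c(10, -10)
  p <- rbm_prob_h_given_v(prm, c(0, 0, 0))[1, ]
  expect_gt(p[1], 0.99)
  expect_lt(p[2], 0.01)
  # random small instance against a direct sigma(.) oracle
  set.seed(22)
  prm <- init_rbm_params(4, 3, init_scale = 0.5)
  prm$A <- rnorm(4); prm$B <- rnorm(3)
  V <- matrix(runif(8), 2, 4)
  expect_equal(rbm_prob_h_given_v(prm, V),
               1 / (1 + exp(-(V %*% prm$U + rep(1, 2) %o% prm$B))),
               tolerance = 1e-12)
})

test_that("CD-1 with zero learning rate leaves parameters unchanged", {
  set.seed(23)
  prm <- init_rbm_params(6, 4)
  data <- matrix(runif(60), 10, 6)
  out <- cd1_epoch(prm, data, lr = 0)
  expect_equal(out$params, prm)
  expect_error(cd1_epoch(prm, data[0, , drop = FALSE]), "empty")
})

test_that("CD-1 training reduces reconstruction error and keeps weights finite", {
  set.seed(24)
  proto <- matrix(rbinom(32, 1, 0.5), 4, 8)
  data <- proto[sample(1:4, 120, replace = TRUE), ] +
    matrix(rnorm(120 * 8, sd = 0.05), 120, 8)
  data <- pmin(pmax(data, 0), 1)
  fit <- train_rbm(data, n_hidden = 12, epochs = 40, batch = 40)
  expect_lt(median(utils::tail(fit$recon_trace, 5)),
            median(utils::head(fit$recon_trace, 5)))
  expect_true(all(is.finite(fit$params$U)))
})

test_that("DBN rejects unscaled input and emits scores in (0,1) deterministically", {
  set.seed(25)
  X <- matrix(runif(80), 20, 4)
  y <- rep(0:1, 10)
  expect_error(train_dbn_predict(X * 2, y), "\\[0, 1\\]")
  cfg <- list(hidden = 8L, pretrain_epochs = 3L, finetune_epochs = 5L, seed = 7)
  m1 <- train_dbn_predict(X, y, cfg)
  m2 <- train_dbn_predict(X, y, cfg)
  expect_true(all(m1$scores > 0 & m1$scores < 1))
  expect_identical(m1$scores, m2$scores)
  expect_equal(dbn_predict(m1, X), m1$scores)
})

test_that("fine-tuning reduces the cross-entropy on separable data", {
  set.seed(26)
  N <- 80
  y <- rep(0:1, each = N / 2)
  X <- matrix(runif(N * 6), N, 6)
  X[, 1] <- 0.1 + 0.7 * y + runif(N) * 0.2
  m <- train_dbn_predict(X, y, list(hidden = 10L, pretrain_epochs = 10L,
                                    finetune_epochs = 60L, seed = 3))
  expect_lt(m$finetune_trace[length(m$finetune_trace)], m$finetune_trace[1])
})
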