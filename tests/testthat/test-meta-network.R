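test_that("self-attention matches a naive dense evaluation", {
  set.seed(50)
  Q <- matrix(rnorm(12), 3, 4)
  K <- matrix(rnorm(12), 3, 4)
  V <- matrix(rnorm(12), 3, 4)
  expect_equal(self_attention(Q, K, V), naive_attention(Q, K, V),
               tolerance = 1e-6)
  # single timestep: softmax over one element is 1
  expect_equal(self_attention(Q[1, , drop = FALSE],
                              K[1, , drop = FALSE],
                              V[1, , drop = FALSE]),
               V[1, , drop = FALSE])
  # zero queries: uniform weights, every row the column mean of V
  Z <- self_attention(Q * 0, K, V)
  for (i in 1:3) expect_equal(Z[i, ], colMeans(V), tolerance = 1e-12)
  expect_error(self_attention(Q[, 0], K[, 0], V[, 0]), "d_k")
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(51)
  for (att in c(TRUE, FALSE)) {
    cfg <- network_config(hidden_units = 3, epochs = 1, seed = 5,
                          attention = att)
    X <- matrix(rnorm(5 * 4), 5, 4)
    y <- c(1, 0, 1, 0, 1)
    p <- emdeepsd:::init_network_params(cfg)
    fw <- emdeepsd:::network_forward(p, cfg, X, keep_cache = TRUE)
    ga <- emdeepsd:::flatten_params(
      emdeepsd:::network_backward(p, cfg, fw, y))
    f0 <- emdeepsd:::flatten_params(p)
    loss_at <- function(fl) {
      pp <- emdeepsd:::relist_params(fl, p)
      emdeepsd:::bce_loss(
        emdeepsd:::network_forward(pp, cfg, X)$p, y)
    }
    eps <- 1e-6
    gn <- vapply(seq_along(f0), function(i) {
      a <- f0; a[i] <- a[i] + eps
      b <- f0; b[i] <- b[i] - eps
      (loss_at(a) - loss_at(b)) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(ga - gn)), 1e-7)
  }
})

test_that("zero weights give probability one half and outputs stay in (0,1)", {
  cfg <- network_config(hidden_units = 4, seed = 1)
  p <- emdeepsd:::init_network_params(cfg)
  pz <- rapply(p, function(m) m * 0, how = "replace")
  set.seed(52)
  X <- matrix(rnorm(6 * 10), 6, 10)
  expect_equal(emdeepsd:::network_forward(pz, cfg, X)$p, rep(0.5, 6))
  pr <- emdeepsd:::network_forward(p, cfg, X)$p
  expect_true(all(pr > 0 & pr < 1))
})

test_that("a gate with zero weights activates at sigmoid of its bias", {
  # closed-form check of the gate equation on the first LSTM layer
  cfg <- network_config(hidden_units = 2, seed = 2)
  p <- emdeepsd:::init_network_params(cfg)
  p$lstm[[1]]$W_x[] <- 0
  p$lstm[[1]]$W_h[] <- 0
  b <- c(0.3, -1.2, 0.5, 0.8, -0.4, 0.1, 0.25, -0.6)
  p$lstm[[1]]$b <- b
  fw <- emdeepsd:::lstm_layer_forward(list(matrix(0, 1, 1)),
                                      p$lstm[[1]], 2)
  cc <- fw$cache[[1]]
  expect_equal(as.numeric(cc$f), 1 / (1 + exp(-b[1:2])))
  expect_equal(as.numeric(cc$i), 1 / (1 + exp(-b[3:4])))
  expect_equal(as.numeric(cc$o), 1 / (1 + exp(-b[5:6])))
  expect_equal(as.numeric(cc$g), tanh(b[7:8]))
})

test_that("training reduces the loss and separates a stacked fixture", {
  set.seed(53)
  n <- 120
  X <- matrix(rnorm(n * 15), n, 15)
  y <- rep(1:0, each = n / 2)
  X[y == 1, ] <- X[y == 1, ] + 1.2
  colnames(X) <- paste0("m", 1:15)
  net <- train_network(X, y, network_config(hidden_units = 20,
                                            seed = 3))
  expect_lt(net$loss_history[50], net$loss_history[1])
  expect_gte(auc_score(y, predict(net, X)), 0.95)
  # reproducibility under the same seed
  net2 <- train_network(X, y, network_config(hidden_units = 20,
                                             seed = 3))
  expect_lt(abs(tail(net$loss_history, 1) -
                  tail(net2$loss_history, 1)), 1e-6)
  expect_error(train_network(X, rep(1, n)), "single class")
})

test_that("prediction enforces the recorded manifest", {
  set.seed(54)
  X <- matrix(rnorm(40 * 6), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- rep(0:1, 20)
  net <- train_network(X, y, network_config(hidden_units = 4,
                                            epochs = 5, seed = 4))
  p <- predict(net, X)
  expect_length(p, 40)
  expect_true(all(p > 0 & p < 1))
  expect_error(predict(net, X[, 1:5]), "meta-feature columns")
  shuffled <- X[, c(2, 1, 3:6)]
  expect_error(predict(net, shuffled), "manifest")
})

test_that("with one timestep and no attention the head is logistic regression on the LSTM output", {
  cfg <- network_config(hidden_units = 2, attention = FALSE, seed = 6)
  p <- emdeepsd:::init_network_params(cfg)
  X <- matrix(c(0.4), 1, 1)
  fw <- emdeepsd:::network_forward(p, cfg, X, keep_cache = TRUE)
  h <- fw$Y[1, 1, ]  # pooled single-timestep LSTM output
  expect_equal(fw$p,
               1 / (1 + exp(-(sum(h * p$dense$w) + p$dense$b))),
               tolerance = 1e-12)
})
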