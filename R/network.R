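# Deep-learning module: a two-layer LSTM over the stacked base-learner
# probabilities (one timestep per model, feature dimension 1), a
# self-attention layer, global average pooling over timesteps, and a
# sigmoid dense head. Forward, analytic backpropagation and Adam are
# implemented directly on base-R matrices, so training is deterministic
# given the seed.

#' Scaled dot-product self-attention
#'
#' `SelfAttn(Q, K, V) = softmax(Q K' / sqrt(d_k)) V` with the softmax
#' taken row-wise, so every output row is a convex combination of V's
#' rows.
#'
#' @param Q,K,V timestep x d_k matrices.
#' @return timestep x d_k matrix.
#' @export
self_attention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  d_k <- ncol(K)
  if (d_k == 0) stop("d_k must be positive")
  stopifnot(ncol(Q) == d_k, nrow(K) == nrow(V))
  S <- Q %*% t(K) / sqrt(d_k)
  A <- exp(S - apply(S, 1, max))
  A <- A / rowSums(A)
  A %*% V
}

# ---- parameter initialisation ---------------------------------------

#' Meta-network configuration
#'
#' @param hidden_units LSTM units per layer (20 for the SSA stack, 10
#'   for the EMD stack).
#' @param lstm_layers number of stacked LSTM layers (default 2).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 64; a final partial batch
#'   is allowed).
#' @param attention include the self-attention layer (default TRUE;
#'   FALSE gives the ablated architecture that pools the LSTM output
#'   directly).
#' @param seed seed for weight initialisation and batch shuffling.
#' @return list of class `network_config`.
#' @export
network_config <- function(hidden_units = 20, lstm_layers = 2,
                           learning_rate = 0.001, epochs = 50,
                           batch_size = 64, attention = TRUE,
                           seed = 1L) {
  stopifnot(hidden_units > 0, epochs >= 1, lstm_layers >= 1)
  structure(list(hidden_units = hidden_units,
                 lstm_layers = lstm_layers,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, attention = attention,
                 seed = seed),
            class = "network_config")
}

# Gate column blocks are ordered [forget | input | output | candidate].
init_network_params <- function(config) {
  H <- config$hidden_units
  u <- function(nr, nc) {
    matrix(stats::runif(nr * nc, -0.1, 0.1), nr, nc)
  }
  with_seed(config$seed, {
    lstm <- lapply(seq_len(config$lstm_layers), function(l) {
      d_in <- if (l == 1) 1L else H
      b <- stats::runif(4 * H, -0.1, 0.1)
      b[seq_len(H)] <- 1  # forget-gate bias starts open
      list(W_x = u(d_in, 4 * H), W_h = u(H, 4 * H), b = b)
    })
    params <- list(lstm = lstm)
    if (config$attention) {
      params$att <- list(Wq = u(H, H), Wk = u(H, H), Wv = u(H, H))
    }
    params$dense <- list(w = stats::runif(H, -0.1, 0.1),
                         b = stats::runif(1, -0.1, 0.1))
    params
  })
}

# ---- forward / backward ---------------------------------------------

# One LSTM layer over a batch. xs: list of T matrices (B x d_in).
# Returns hs (list of T matrices B x H) and caches for backprop.
lstm_layer_forward <- function(xs, layer, H) {
  T_len <- length(xs)
  B <- nrow(xs[[1]])
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  hs <- vector("list", T_len); cache <- vector("list", T_len)
  idx <- function(k) ((k - 1) * H + 1):(k * H)
  for (t in seq_len(T_len)) {
    A <- xs[[t]] %*% layer$W_x + h %*% layer$W_h +
      matrix(layer$b, B, 4 * H, byrow = TRUE)
    f <- sigmoid(A[, idx(1), drop = FALSE])
    i <- sigmoid(A[, idx(2), drop = FALSE])
    o <- sigmoid(A[, idx(3), drop = FALSE])
    g <- tanh(A[, idx(4), drop = FALSE])
    c_new <- f * cc + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc,
                       f = f, i = i, o = o, g = g, tc = tc)
    h <- h_new; cc <- c_new
    hs[[t]] <- h
  }
  list(hs = hs, cache = cache)
}

# Backward through one LSTM layer. dhs: list of T matrices (B x H) of
# gradients w.r.t. the layer's hidden outputs.
lstm_layer_backward <- function(dhs, layer, cache, H) {
  T_len <- length(dhs)
  B <- nrow(dhs[[1]])
  dW_x <- layer$W_x * 0; dW_h <- layer$W_h * 0; db <- layer$b * 0
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  dxs <- vector("list", T_len)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    do_ <- dh * cc$tc
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dA <- cbind(df * cc$f * (1 - cc$f),
                di * cc$i * (1 - cc$i),
                do_ * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dW_x <- dW_x + t(cc$x) %*% dA
    dW_h <- dW_h + t(cc$h_prev) %*% dA
    db <- db + colSums(dA)
    dxs[[t]] <- dA %*% t(layer$W_x)
    dh_next <- dA %*% t(layer$W_h)
    dc_next <- dc * cc$f
  }
  list(dxs = dxs, grads = list(W_x = dW_x, W_h = dW_h, b = db))
}

# Full forward pass. Xn: B x T normalized meta-features. Returns the
# probabilities and, when keep_cache, everything backprop needs.
network_forward <- function(params, config, Xn, keep_cache = FALSE) {
  B <- nrow(Xn); T_len <- ncol(Xn); H <- config$hidden_units
  xs <- lapply(seq_len(T_len), function(t) Xn[, t, drop = FALSE])
  layer_caches <- vector("list", length(params$lstm))
  for (l in seq_along(params$lstm)) {
    fw <- lstm_layer_forward(xs, params$lstm[[l]], H)
    layer_caches[[l]] <- fw$cache
    xs <- fw$hs
  }
  # per-sample T x H LSTM output
  Y <- array(0, c(T_len, B, H))
  for (t in seq_len(T_len)) Y[t, , ] <- xs[[t]]
  att_cache <- NULL
  if (config$attention) {
    Z <- array(0, c(T_len, B, H))
    att_cache <- vector("list", B)
    for (s in seq_len(B)) {
      Ys <- matrix(Y[, s, ], T_len, H)
      Q <- Ys %*% params$att$Wq
      K <- Ys %*% params$att$Wk
      V <- Ys %*% params$att$Wv
      S <- Q %*% t(K) / sqrt(H)
      A <- exp(S - apply(S, 1, max))
      A <- A / rowSums(A)
      Z[, s, ] <- A %*% V
      if (keep_cache) att_cache[[s]] <- list(Y = Ys, Q = Q, K = K,
                                             V = V, A = A)
    }
  } else {
    Z <- Y
  }
  Zbar <- matrix(0, B, H)  # global average pooling over timesteps
  for (s in seq_len(B)) {
    Zbar[s, ] <- colMeans(matrix(Z[, s, ], T_len, H))
  }
  u <- as.numeric(Zbar %*% params$dense$w) + params$dense$b
  p <- sigmoid(u)
  if (!keep_cache) return(list(p = p))
  list(p = p, xs_in = Xn, layer_caches = layer_caches, Y = Y,
       att_cache = att_cache, Zbar = Zbar, T_len = T_len, B = B)
}

# Gradients of the mean binary cross-entropy on one batch.
network_backward <- function(params, config, fw, y) {
  B <- fw$B; T_len <- fw$T_len; H <- config$hidden_units
  du <- (fw$p - y) / B
  g_dense <- list(w = as.numeric(t(fw$Zbar) %*% du), b = sum(du))
  dZbar <- outer(du, params$dense$w)          # B x H
  g_att <- NULL
  dY <- array(0, c(T_len, B, H))
  if (config$attention) {
    g_att <- list(Wq = params$att$Wq * 0, Wk = params$att$Wk * 0,
                  Wv = params$att$Wv * 0)
    for (s in seq_len(B)) {
      ac <- fw$att_cache[[s]]
      dZ <- matrix(rep(dZbar[s, ] / T_len, each = T_len), T_len, H)
      dA <- dZ %*% t(ac$V)
      dV <- t(ac$A) %*% dZ
      dS <- ac$A * (dA - rowSums(dA * ac$A))
      dQ <- dS %*% ac$K / sqrt(H)
      dK <- t(dS) %*% ac$Q / sqrt(H)
      g_att$Wq <- g_att$Wq + t(ac$Y) %*% dQ
      g_att$Wk <- g_att$Wk + t(ac$Y) %*% dK
      g_att$Wv <- g_att$Wv + t(ac$Y) %*% dV
      dY[, s, ] <- dQ %*% t(params$att$Wq) + dK %*% t(params$att$Wk) +
        dV %*% t(params$att$Wv)
    }
  } else {
    for (s in seq_len(B)) {
      dY[, s, ] <- matrix(rep(dZbar[s, ] / T_len, each = T_len),
                          T_len, H)
    }
  }
  dhs <- lapply(seq_len(T_len), function(t) matrix(dY[t, , ], B, H))
  g_lstm <- vector("list", length(params$lstm))
  for (l in rev(seq_along(params$lstm))) {
    bw <- lstm_layer_backward(dhs, params$lstm[[l]],
                              fw$layer_caches[[l]], H)
    g_lstm[[l]] <- bw$grads
    dhs <- bw$dxs
  }
  list(lstm = g_lstm, att = g_att, dense = g_dense)
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# ---- flat parameter utilities (Adam, gradient checks) ---------------

flatten_params <- function(p) {
  unlist(p, use.names = FALSE)
}

relist_params <- function(flat, skeleton) {
  utils::relist(flat, skeleton)
}

#' Train the LSTM/self-attention meta-network
#'
#' Z-score normalizes the meta-feature columns (statistics frozen from
#' the training data), treats each sample's vector of base-learner
#' probabilities as a sequence of one-dimensional timesteps, and
#' minimizes binary cross-entropy with Adam. Deterministic given
#' `config$seed`.
#'
#' @param X samples x n_models meta-feature matrix (column names are
#'   recorded as the input manifest).
#' @param y binary labels (both classes required).
#' @param config a [network_config()].
#' @return object of class `trained_network` with the learned weights,
#'   the config, the column `manifest`, the normalization statistics
#'   and the per-epoch loss history.
#' @export
train_network <- function(X, y, config = network_config()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("labels contain a single class")
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | !is.finite(sd_)] <- 1
  Xn <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  params <- init_network_params(config)
  flat <- flatten_params(params)
  m <- numeric(length(flat)); v <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(config$epochs)
  n <- nrow(Xn)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      batch_losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        fw <- network_forward(params, config,
                              Xn[idx, , drop = FALSE],
                              keep_cache = TRUE)
        gr <- network_backward(params, config, fw, y[idx])
        batch_losses <- c(batch_losses, bce_loss(fw$p, y[idx]))
        step <- step + 1L
        gflat <- flatten_params(gr)
        m <- beta1 * m + (1 - beta1) * gflat
        v <- beta2 * v + (1 - beta2) * gflat^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        flat <- flatten_params(params) -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
        params <- relist_params(flat, params)
      }
      loss_hist[epoch] <- mean(batch_losses)
    }
  })
  structure(list(params = params, config = config,
                 manifest = colnames(X),
                 norm = list(mu = mu, sd = sd_),
                 loss_history = loss_hist),
            class = "trained_network")
}

#' Predict cancer probabilities with a trained meta-network
#'
#' Applies the stored normalization and the forward pass. The columns
#' of `X` must match the training manifest (same models, same order);
#' a mismatch is an error, never silently reordered.
#'
#' @param object a `trained_network`.
#' @param X samples x n_models meta-feature matrix.
#' @param ... unused.
#' @return probabilities strictly in (0, 1).
#' @export
predict.trained_network <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$manifest)) {
    stop("expected ", length(object$manifest),
         " meta-feature columns (manifest: ",
         paste(utils::head(object$manifest, 3), collapse = ", "),
         ", ...)")
  }
  if (!is.null(colnames(X)) &&
      !identical(colnames(X), object$manifest)) {
    stop("meta-feature columns do not match the training manifest")
  }
  Xn <- sweep(sweep(X, 2, object$norm$mu), 2, object$norm$sd, "/")
  network_forward(object$params, object$config, Xn)$p
}

#' @export
print.trained_network <- function(x, ...) {
  cat("Trained meta-network:", x$config$lstm_layers, "LSTM layers x",
      x$config$hidden_units, "units,",
      if (x$config$attention) "with" else "without",
      "self-attention\n")
  cat("  inputs:", length(x$manifest), "meta-features; final loss:",
      format(utils::tail(x$loss_history, 1), digits = 4), "\n")
  invisible(x)
}
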