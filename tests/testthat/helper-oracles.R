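# Independent oracles and small fixtures used across the test files.
# Each oracle is a deliberately naive implementation kept separate from
# the package's code paths.

# O(n^2) pair-counting AUC with 0.5 tie credit.
pair_count_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (p in pos) {
    for (n in neg) {
      total <- total + (p > n) + 0.5 * (p == n)
    }
  }
  total / (length(pos) * length(neg))
}

# Exhaustive active-set NNLS: solve unconstrained least squares on every
# subset of columns, keep feasible (non-negative) solutions, return the
# one with the smallest residual.
brute_force_nnls <- function(A, b) {
  k <- ncol(A)
  best <- list(x = numeric(k), resid = sqrt(sum(b^2)))
  for (mask in seq_len(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    As <- A[, sel, drop = FALSE]
    coef <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(coef) || any(coef < 0)) next
    r <- sqrt(sum((As %*% coef - b)^2))
    if (r < best$resid - 1e-12) {
      x <- numeric(k)
      x[sel] <- coef
      best <- list(x = x, resid = r)
    }
  }
  best
}

# Textbook SSA through the eigen decomposition of the lag-covariance
# matrix S = X X' (a different code path from the package's SVD).
eigen_ssa <- function(series, L, grouping) {
  N <- length(series)
  K <- N - L + 1
  X <- outer(seq_len(L), seq_len(K), function(i, j) series[i + j - 1])
  eg <- eigen(X %*% t(X), symmetric = TRUE)
  hankelize <- function(M) {
    i <- row(M) + col(M) - 1
    as.numeric(tapply(as.vector(M), as.vector(i), mean))
  }
  lapply(grouping, function(g) {
    U <- eg$vectors[, g, drop = FALSE]
    hankelize(U %*% t(U) %*% X)
  })
}

# Sign-flip permutation test for the difference of two paired AUCs.
perm_auc_test <- function(y, a, b, n_perm = 10000, seed = 1) {
  obs <- abs(auc_score(y, a) - auc_score(y, b))
  set.seed(seed)
  n <- length(y)
  cnt <- 0L
  for (i in seq_len(n_perm)) {
    sw <- stats::runif(n) < 0.5
    aa <- ifelse(sw, b, a)
    bb <- ifelse(sw, a, b)
    if (abs(auc_score(y, aa) - auc_score(y, bb)) >= obs - 1e-12) {
      cnt <- cnt + 1L
    }
  }
  cnt / n_perm
}

# Dense evaluation of scaled dot-product attention, element by element.
naive_attention <- function(Q, K, V) {
  T_len <- nrow(Q)
  d_k <- ncol(K)
  out <- matrix(0, T_len, ncol(V))
  for (i in seq_len(T_len)) {
    s <- numeric(nrow(K))
    for (j in seq_len(nrow(K))) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d_k)
    w <- exp(s) / sum(exp(s))
    for (c in seq_len(ncol(V))) out[i, c] <- sum(w * V[, c])
  }
  out
}

baseline_profile_fixture <- function() emdeepsd:::baseline_profile()

# A 12-bp palindromic-friendly toy reference used by extraction tests.
toy_reference <- function() {
  c(chrT = "ACGTACGTACGT")
}

write_bed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  path
}
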