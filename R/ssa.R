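# Singular spectrum analysis of a 256-point end-motif series.

#' Embed a series into its Hankel trajectory matrix
#'
#' Builds the L x K trajectory matrix whose columns are the K = N - L + 1
#' lagged windows of the series; entry (i, j) is `series[i + j - 1]`.
#'
#' @param series numeric vector of length N.
#' @param L window length, 2 <= L <= floor(N / 2).
#' @return L x K numeric matrix.
#' @export
ssa_embed <- function(series, L) {
  N <- length(series)
  if (L < 2 || L > floor(N / 2)) {
    stop("window length must satisfy 2 <= L <= floor(N/2); got L = ", L,
         ", N = ", N)
  }
  K <- N - L + 1L
  outer(seq_len(L), seq_len(K), function(i, j) series[i + j - 1L])
}

# Anti-diagonal (Hankel) averaging of an L x K matrix back to a length-N
# series: position n averages all entries with i + j - 1 == n.
diagonal_average <- function(M) {
  L <- nrow(M); K <- ncol(M); N <- L + K - 1L
  i <- row(M) + col(M) - 1L
  sums <- vapply(split(as.vector(M), as.vector(i)), sum, numeric(1))
  cnt <- tabulate(as.vector(i), nbins = N)
  as.numeric(sums[as.character(seq_len(N))]) / cnt
}

#' Singular spectrum analysis decomposition
#'
#' Embeds the series (window `L`), takes the SVD of the trajectory
#' matrix, groups the L elementary components by index, and
#' anti-diagonally averages each group's rank-sum back to a length-N
#' subsequence. The default grouping \{1\}, \{2,3\}, \{4..8\} yields three
#' subsequences: SSA1 carries the primary trend, SSA2 local
#' peaks/troughs, SSA3 fine fluctuations. The group sums reconstruct the
#' input exactly (completeness of the SVD).
#'
#' @param series numeric vector (an end-motif profile, N = 256).
#' @param L window length (default 8).
#' @param grouping list of integer index sets partitioning `1:L`.
#' @return object of class `ssa_decomposition`: `subsequences` (list of
#'   length-N series, one per group), `lambda` (the L eigenvalues of the
#'   lag-covariance matrix X X', non-increasing), `grouping`, `L`.
#' @export
ssa_decompose <- function(series, L = 8,
                          grouping = list(1L, 2:3, 4:8)) {
  X <- ssa_embed(series, L)
  idx <- sort(unlist(grouping))
  if (!identical(as.integer(idx), seq_len(L))) {
    stop("grouping must partition 1:", L)
  }
  sv <- svd(X)
  lambda <- sv$d^2  # eigenvalues of X X', non-increasing
  subsequences <- lapply(grouping, function(g) {
    Xg <- sv$u[, g, drop = FALSE] %*%
      (sv$d[g] * t(sv$v[, g, drop = FALSE]))
    diagonal_average(Xg)
  })
  names(subsequences) <- paste0("SSA", seq_along(subsequences))
  structure(list(subsequences = subsequences, lambda = lambda,
                 grouping = grouping, L = L),
            class = "ssa_decomposition")
}

#' @export
print.ssa_decomposition <- function(x, ...) {
  cat("SSA decomposition: L =", x$L, ",",
      length(x$subsequences), "subsequences\n")
  cat("  eigenvalue shares:",
      paste(sprintf("%.3f", x$lambda / sum(x$lambda)), collapse = " "),
      "\n")
  invisible(x)
}
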