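# Empirical mode decomposition of an end-motif series, with permutation
# entropy regrouping of the intrinsic mode functions (IMFs).

# Interior local extrema; plateaus collapse to their right edge.
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(), minima = integer()))
  s <- sign(diff(x))
  nz <- s != 0
  if (!any(nz)) return(list(maxima = integer(), minima = integer()))
  # carry the previous non-zero slope through plateaus
  filled <- s
  last <- 0
  for (i in seq_along(filled)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  maxima <- integer(); minima <- integer()
  for (i in seq_len(n - 2L)) {
    if (filled[i] > 0 && filled[i + 1L] < 0) maxima <- c(maxima, i + 1L)
    if (filled[i] < 0 && filled[i + 1L] > 0) minima <- c(minima, i + 1L)
  }
  list(maxima = maxima, minima = minima)
}

count_zero_crossings <- function(x) {
  x <- x[x != 0]
  if (length(x) < 2) return(0L)
  sum(diff(sign(x)) != 0)
}

# Cubic spline envelope through extrema, mirror-extending two extrema
# beyond each boundary so the spline is anchored outside the support.
spline_envelope <- function(idx, val, n) {
  k <- min(2L, length(idx))
  left_i <- 2 - rev(idx[seq_len(k)])
  left_v <- rev(val[seq_len(k)])
  right_i <- 2 * n - rev(idx)[seq_len(k)]
  right_v <- rev(val)[seq_len(k)]
  xi <- c(left_i, idx, rev(right_i))
  yi <- c(left_v, val, rev(right_v))
  keep <- !duplicated(xi)
  f <- stats::splinefun(xi[keep], yi[keep], method = "natural")
  f(seq_len(n))
}

# Sift one IMF out of `x`. Accepts when the zero/extrema counts differ by
# at most one and the mean envelope is locally small (|E| < amp_tol times
# the local amplitude, with a Cauchy-style relative-change fallback).
sift_one_imf <- function(x, max_sift_iter = 100, amp_tol = 0.05,
                         sd_tol = 0.2) {
  n <- length(x)
  h <- x
  for (iter in seq_len(max_sift_iter)) {
    ext <- local_extrema(h)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    upper <- spline_envelope(ext$maxima, h[ext$maxima], n)
    lower <- spline_envelope(ext$minima, h[ext$minima], n)
    m <- (upper + lower) / 2
    amp <- (upper - lower) / 2
    h_new <- h - m
    ext_new <- local_extrema(h_new)
    n_ext <- length(ext_new$maxima) + length(ext_new$minima)
    n_zero <- count_zero_crossings(h_new)
    counts_ok <- abs(n_zero - n_ext) <= 1
    env_ok <- all(abs(m) <= amp_tol * pmax(abs(amp), 1e-12))
    sd_ok <- sum(m^2) / max(sum(h^2), 1e-300) < sd_tol * amp_tol
    h <- h_new
    if (counts_ok && (env_ok || sd_ok)) break
  }
  h
}

#' Empirical mode decomposition by sifting
#'
#' Adaptively decomposes a series into intrinsic mode functions (IMFs)
#' and a residual. Each IMF is extracted by repeated sifting: cubic
#' spline envelopes through the local maxima and minima (mirror-extended
#' at the boundaries), subtraction of the envelope mean, until the
#' zero-crossing and extrema counts agree to within one and the envelope
#' mean is locally negligible. Decomposition stops when the residual has
#' fewer than two interior maxima or minima (a monotone trend) or falls
#' below the amplitude floor. By construction of the successive
#' subtractions, `Reduce("+", imfs) + residual` reproduces the input.
#'
#' @param series numeric vector, length >= 8.
#' @param max_imfs maximum number of IMFs to extract (default 10).
#' @param max_sift_iter sifting iteration cap per IMF (default 100).
#' @return object of class `emd_decomposition`: `imfs` (list, possibly
#'   empty), `residual`.
#' @export
sift_emd <- function(series, max_imfs = 10, max_sift_iter = 100) {
  if (length(series) < 8) stop("series too short for EMD (need >= 8)")
  amp_floor <- 1e-10 * max(diff(range(series)), 1e-300)
  residual <- series
  imfs <- list()
  for (m in seq_len(max_imfs)) {
    ext <- local_extrema(residual)
    if (length(ext$maxima) < 2 || length(ext$minima) < 2) break
    if (diff(range(residual)) < amp_floor) break
    imf <- sift_one_imf(residual, max_sift_iter = max_sift_iter)
    if (all(imf == 0)) break
    imfs[[length(imfs) + 1L]] <- imf
    residual <- residual - imf
  }
  if (length(imfs)) names(imfs) <- paste0("IMF", seq_along(imfs))
  structure(list(imfs = imfs, residual = residual),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat("EMD decomposition:", length(x$imfs), "IMFs + residual\n")
  invisible(x)
}

#' Normalized permutation entropy of a series
#'
#' Shannon entropy of the ordinal-pattern distribution over sliding
#' windows of `m` points at delay `tau`, normalized by `log(m!)` so the
#' value lies in \[0, 1\]. Ties within a window are broken by index
#' order (stable), so constant and monotone series both score 0.
#'
#' @param series numeric vector of length >= `m * tau + 1`.
#' @param m embedding order (default 4: 24 patterns, well estimated from
#'   a 256-point profile).
#' @param tau delay (default 1).
#' @return entropy in \[0, 1\].
#' @export
permutation_entropy <- function(series, m = 4, tau = 1) {
  n <- length(series)
  if (n < m * tau + 1) {
    stop("series too short for permutation entropy: need length >= ",
         m * tau + 1)
  }
  n_win <- n - (m - 1L) * tau
  offs <- (seq_len(m) - 1L) * tau
  W <- vapply(offs, function(o) series[seq_len(n_win) + o],
              numeric(n_win))
  pats <- apply(W, 1L, function(w) paste(order(w), collapse = "."))
  p <- tabulate(factor(pats))
  p <- p / sum(p)
  as.numeric(-sum(p * log(p)) / log(factorial(m)))
}

#' Regroup IMFs into high- and low-entropy subsequences
#'
#' Pools the IMFs of an EMD by permutation entropy: EMD1 sums the IMFs
#' with PE >= `threshold` (the fast, noise-like modes) and EMD2 sums the
#' remaining IMFs plus the residual (the trend). The two always sum back
#' to the original series; either may be identically zero.
#'
#' @param decomposition an `emd_decomposition` from [sift_emd()].
#' @param threshold PE cut point (default 0.8).
#' @param m,tau permutation-entropy parameters.
#' @return list with `EMD1`, `EMD2` (length-N series) and `pe` (PE per
#'   IMF).
#' @export
regroup_by_pe <- function(decomposition, threshold = 0.8, m = 4,
                          tau = 1) {
  stopifnot(inherits(decomposition, "emd_decomposition"))
  n <- length(decomposition$residual)
  pe <- vapply(decomposition$imfs, permutation_entropy, numeric(1),
               m = m, tau = tau)
  high <- pe >= threshold
  zero <- numeric(n)
  e1 <- if (any(high)) Reduce(`+`, decomposition$imfs[high]) else zero
  e2 <- Reduce(`+`, c(decomposition$imfs[!high],
                      list(decomposition$residual)))
  list(EMD1 = e1, EMD2 = e2, pe = pe)
}

#' EMD decomposition of a profile into the two PE-pooled subsequences
#'
#' Convenience wrapper: [sift_emd()] followed by [regroup_by_pe()].
#'
#' @inheritParams sift_emd
#' @inheritParams regroup_by_pe
#' @return list with `subsequences` (list `EMD1`, `EMD2`), `pe`,
#'   `n_imfs`.
#' @export
emd_decompose <- function(series, threshold = 0.8, max_imfs = 10,
                          max_sift_iter = 100) {
  dec <- sift_emd(series, max_imfs = max_imfs,
                  max_sift_iter = max_sift_iter)
  rg <- regroup_by_pe(dec, threshold = threshold)
  list(subsequences = list(EMD1 = rg$EMD1, EMD2 = rg$EMD2),
       pe = rg$pe, n_imfs = length(dec$imfs))
}
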