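# Motif diversity scores (MDS, MDS-SDs) and founder-profile
# deconvolution.

#' Motif diversity score (normalized Shannon entropy)
#'
#' `MDS = sum_i -P_i log(P_i) / log(256)` over the 256 motif
#' frequencies, with `0 log 0 := 0`. The theoretical scale runs from 0
#' (all fragment ends share one motif) to 1 (uniform motif usage).
#'
#' @param frequencies numeric vector of 256 non-negative frequencies
#'   summing to 1 (tolerance 1e-6).
#' @return score in \[0, 1\].
#' @examples
#' mds(rep(1 / 256, 256))  # 1
#' @export
mds <- function(frequencies) {
  if (inherits(frequencies, "end_motif_profile")) {
    frequencies <- frequencies$frequencies
  }
  if (length(frequencies) != 256L) stop("expected 256 motif frequencies")
  if (any(frequencies < 0)) stop("negative motif frequency")
  if (abs(sum(frequencies) - 1) > 1e-6) {
    stop("frequencies must sum to 1 (got ", sum(frequencies), ")")
  }
  p <- frequencies[frequencies > 0]
  as.numeric(-sum(p * log(p)) / log(256))
}

#' Softmax normalization of a decomposition subsequence
#'
#' Maps any finite 256-point series to a strictly positive frequency
#' vector summing to 1: `Z_i = exp(Q_i) / sum_j exp(Q_j)`. Computed with
#' max-subtraction, so it is numerically stable and exactly
#' shift-invariant. Decomposition subsequences can be negative; this is
#' the step that makes the entropy in [mds_sub()] well defined.
#'
#' @param q numeric vector of finite values.
#' @return vector of the same length, in (0, 1), summing to 1.
#' @export
softmax_normalize <- function(q) {
  if (any(!is.finite(q))) stop("non-finite value in softmax input")
  e <- exp(q - max(q))
  e / sum(e)
}

#' Diversity score of a decomposition subsequence
#'
#' The subsequence is softmax-normalized and its normalized Shannon
#' entropy taken: `MDS_Sub = sum_i -Z_i log(Z_i) / log(256)`. Exactly
#' `mds(softmax_normalize(q))`.
#'
#' @param subsequence numeric vector of 256 finite values (negatives
#'   allowed).
#' @return score in (0, 1\].
#' @export
mds_sub <- function(subsequence) {
  mds(softmax_normalize(subsequence))
}

#' Composite diversity score over the three SSA subsequences
#'
#' Weighted mean of the SSA1-SSA3 subsequence scores, the weight of each
#' group being its share of the total SSA eigenvalue mass: with default
#' grouping \{1\}, \{2,3\}, \{4..8\}, `w1 = l1 / sum(l)`,
#' `w2 = (l2 + l3) / sum(l)`, `w3 = (l4 + ... + l8) / sum(l)`.
#'
#' @param sub_scores numeric vector of 3 subsequence scores (SSA1-SSA3).
#' @param lambda the non-increasing SSA eigenvalues (length >= 4).
#' @param grouping the index grouping used in the decomposition.
#' @return weighted score in \[0, 1\].
#' @export
mds_ssa <- function(sub_scores, lambda,
                    grouping = list(1L, 2:3, 4:8)) {
  stopifnot(length(sub_scores) == length(grouping))
  if (sum(lambda) <= 0) stop("all-zero singular values")
  w <- vapply(grouping, function(g) sum(lambda[g]), numeric(1)) /
    sum(lambda)
  as.numeric(sum(w * sub_scores))
}

#' Composite diversity score over the two EMD subsequences
#'
#' Arithmetic mean of the EMD1 and EMD2 subsequence scores.
#'
#' @param sub_scores numeric vector of 2 subsequence scores.
#' @return mean score.
#' @export
mds_emd <- function(sub_scores) {
  stopifnot(length(sub_scores) == 2L)
  mean(sub_scores)
}

#' All decomposition-based diversity scores of one profile
#'
#' Runs both decompositions and returns MDS, the five subsequence scores
#' (SSA1-3, EMD1-2) and the two composites MDS-SSA and MDS-EMD.
#'
#' @param frequencies 256 motif frequencies (or an `end_motif_profile`).
#' @param L SSA window length.
#' @return named numeric vector with elements `MDS`, `MDS_Sub_SSA1..3`,
#'   `MDS_Sub_EMD1..2`, `MDS_SSA`, `MDS_EMD`.
#' @export
diversity_scores <- function(frequencies, L = 8) {
  if (inherits(frequencies, "end_motif_profile")) {
    frequencies <- frequencies$frequencies
  }
  base <- mds(frequencies)
  ssa <- ssa_decompose(frequencies, L = L)
  emd <- emd_decompose(frequencies)
  s_ssa <- vapply(ssa$subsequences, mds_sub, numeric(1))
  s_emd <- vapply(emd$subsequences, mds_sub, numeric(1))
  c(MDS = base,
    MDS_Sub_SSA1 = s_ssa[[1]], MDS_Sub_SSA2 = s_ssa[[2]],
    MDS_Sub_SSA3 = s_ssa[[3]],
    MDS_Sub_EMD1 = s_emd[[1]], MDS_Sub_EMD2 = s_emd[[2]],
    MDS_SSA = mds_ssa(s_ssa, ssa$lambda, ssa$grouping),
    MDS_EMD = mds_emd(s_emd))
}

#' Founder-profile deconvolution by non-negative least squares
#'
#' Models a sample's end-motif profile as a non-negative mixture of six
#' founder ("F-") profiles and estimates the mixture weights by NNLS:
#' `p = argmin_{p >= 0} || profile - F p ||_2`. Contributions are
#' returned raw and as percentages of their sum.
#'
#' @param profile 256 motif frequencies.
#' @param founders 256 x 6 non-negative matrix, motif rows in
#'   lexicographic order (rownames checked when present).
#' @return list with `p` (6 non-negative weights), `percent`
#'   (`100 * p / sum(p)`), `residual_norm` (Euclidean).
#' @export
deconvolve <- function(profile, founders) {
  if (inherits(profile, "end_motif_profile")) {
    profile <- profile$frequencies
  }
  founders <- as.matrix(founders)
  if (nrow(founders) != 256L || ncol(founders) != 6L) {
    stop("founder matrix must be 256 motifs x 6 profiles")
  }
  if (any(founders < 0)) stop("negative entry in founder matrix")
  if (length(profile) != 256L) stop("expected 256 motif frequencies")
  if (!is.null(rownames(founders)) && !is.null(names(profile)) &&
      !identical(rownames(founders), names(profile))) {
    stop("motif row order of founder matrix does not match the profile")
  }
  fit <- pracma::lsqnonneg(founders, as.numeric(profile))
  p <- fit$x
  names(p) <- colnames(founders) %||% paste0("F", 1:6)
  list(p = p,
       percent = if (sum(p) > 0) 100 * p / sum(p) else p,
       residual_norm = sqrt(fit$resid.norm))
}
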