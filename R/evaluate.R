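# Classification metrics, AUC/DeLong machinery, p-value adjustment, and
# the per-motif differential scan.

#' Confusion-matrix classification metrics
#'
#' Thresholds the scores and reports sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, accuracy `(TP+TN)/n` and the F1 score
#' (harmonic mean of sensitivity and precision). When precision or
#' sensitivity is undefined (no predicted or no true positives), F1 is
#' reported as 0 with a warning.
#'
#' @param y binary labels (1 = cancer).
#' @param scores numeric scores or probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return named list with `sensitivity`, `specificity`, `accuracy`,
#'   `f1`, `threshold` and the confusion counts.
#' @export
confusion_metrics <- function(y, scores, threshold = 0.5) {
  y <- as.integer(y)
  if (length(y) == 0L) stop("empty input")
  stopifnot(length(y) == length(scores), all(y %in% 0:1),
            all(is.finite(scores)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  sen <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spe <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(y)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  if (is.na(ppv) || is.na(sen) || (ppv + sen) == 0) {
    warning("precision or sensitivity undefined; F1 set to 0")
    f1 <- 0
  } else {
    f1 <- 2 * sen * ppv / (sen + ppv)
  }
  list(sensitivity = sen, specificity = spe, accuracy = acc, f1 = f1,
       threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' Rank-based AUC with 0.5 credit for ties; identical to the O(n^2)
#' count of concordant pairs.
#'
#' @param y binary labels (1 = positive).
#' @param scores numeric scores.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(y, scores) {
  y <- as.integer(y)
  stopifnot(length(y) == length(scores), all(y %in% 0:1))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks give the 0.5 tie credit
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a confidence interval
#'
#' Point estimate from [auc_score()]; confidence interval by the DeLong
#' variance estimate (default) or a seeded percentile bootstrap.
#'
#' @param y binary labels.
#' @param scores numeric scores.
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf_level confidence level (default 0.95).
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed bootstrap seed.
#' @return list with `auc`, `ci_low`, `ci_high`, `method`.
#' @export
auc_ci <- function(y, scores, method = c("delong", "bootstrap"),
                   conf_level = 0.95, n_boot = 1000, seed = 1L) {
  method <- match.arg(method)
  a <- auc_score(y, scores)
  y <- as.integer(y)
  if (method == "delong") {
    roc <- pROC::roc(response = y, predictor = as.numeric(scores),
                     levels = c(0, 1), direction = "<", quiet = TRUE)
    ci <- tryCatch(
      as.numeric(pROC::ci.auc(roc, conf.level = conf_level,
                              method = "delong")),
      error = function(e) c(a, a, a))
    if (any(!is.finite(ci))) ci <- c(a, a, a)
    lo <- max(0, ci[1]); hi <- min(1, ci[3])
  } else {
    boots <- with_seed(seed, {
      n <- length(y)
      replicate(n_boot, {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(y[idx])) < 2) NA_real_ else
          auc_score(y[idx], scores[idx])
      })
    })
    qs <- stats::quantile(boots, c((1 - conf_level) / 2,
                                   1 - (1 - conf_level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  list(auc = a, ci_low = lo, ci_high = hi, method = method)
}

#' DeLong test for two correlated AUCs
#'
#' Paired z-test on the difference of the AUCs of two score vectors
#' computed on the same samples, using the DeLong variance of the
#' difference. When both score vectors are identical or the variance of
#' the difference degenerates with equal AUCs, the p-value is 1.
#'
#' @param y binary labels.
#' @param scores_a,scores_b score vectors on the same samples.
#' @return list with `p_value` (two-sided), `auc_a`, `auc_b`.
#' @export
delong_test <- function(y, scores_a, scores_b) {
  if (length(scores_a) != length(scores_b) ||
      length(y) != length(scores_a)) {
    stop("y, scores_a and scores_b must have equal length")
  }
  a1 <- auc_score(y, scores_a)
  a2 <- auc_score(y, scores_b)
  if (isTRUE(all.equal(as.numeric(scores_a), as.numeric(scores_b)))) {
    return(list(p_value = 1, auc_a = a1, auc_b = a2))
  }
  y <- as.integer(y)
  r1 <- pROC::roc(y, as.numeric(scores_a), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  r2 <- pROC::roc(y, as.numeric(scores_b), levels = c(0, 1),
                  direction = "<", quiet = TRUE)
  p <- tryCatch({
    tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
    as.numeric(tst$p.value)
  }, error = function(e) NA_real_)
  if (!is.finite(p)) p <- if (abs(a1 - a2) < 1e-12) 1 else NA_real_
  list(p_value = p, auc_a = a1, auc_b = a2)
}

#' Multiple-testing adjustment
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two
#' procedures used for end-motif analyses: Bonferroni
#' (`min(1, m * p)`) and Benjamini-Hochberg step-up.
#'
#' @param ps p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"benjamini_hochberg"`.
#' @return adjusted p-values, order preserved.
#' @export
adjust_pvalues <- function(ps, method = c("bonferroni",
                                          "benjamini_hochberg")) {
  method <- match.arg(method)
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(ps, method = switch(method,
                                      bonferroni = "bonferroni",
                                      benjamini_hochberg = "BH"))
}

#' Per-motif differential scan between cancer and control
#'
#' Two-sided Wilcoxon rank-sum test of each of the 256 motif
#' frequencies between the two label groups, direction by the sign of
#' the median difference (cancer minus control), with family-wise or
#' FDR adjustment across the 256 tests.
#'
#' @param pm labeled `profile_matrix` (>= 3 samples per group).
#' @param adjust `"bonferroni"` (default) or `"benjamini_hochberg"`.
#' @param alpha significance level on the adjusted p-values.
#' @return object of class `motif_scan`: data.frame `table` (motif,
#'   direction, p, p_adj, significant) plus `n_up`, `n_down`.
#' @export
motif_scan <- function(pm, adjust = "bonferroni", alpha = 0.05) {
  stopifnot(inherits(pm, "profile_matrix"), !is.null(pm$labels))
  y <- pm$labels
  if (min(sum(y == 1), sum(y == 0)) < 3) {
    stop("need at least 3 samples per group")
  }
  cancer <- pm$x[y == 1, , drop = FALSE]
  control <- pm$x[y == 0, , drop = FALSE]
  ps <- numeric(256)
  dir <- character(256)
  exact <- min(nrow(cancer), nrow(control)) < 10
  for (j in seq_len(256)) {
    a <- cancer[, j]; b <- control[, j]
    ps[j] <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
    dir[j] <- if (stats::median(a) >= stats::median(b)) "up" else "down"
  }
  ps[!is.finite(ps)] <- 1
  p_adj <- adjust_pvalues(ps, adjust)
  sig <- p_adj < alpha
  tab <- data.frame(motif = colnames(pm$x), direction = dir, p = ps,
                    p_adj = p_adj, significant = sig)
  structure(list(table = tab,
                 n_up = sum(sig & dir == "up"),
                 n_down = sum(sig & dir == "down"),
                 adjust = adjust, alpha = alpha),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat("Motif scan (", x$adjust, ", alpha = ", x$alpha, "): ",
      x$n_up, " up, ", x$n_down, " down of 256 motifs\n", sep = "")
  invisible(x)
}

#' Full evaluation report for a score vector
#'
#' @param y binary labels.
#' @param scores probabilities or scores.
#' @param threshold decision threshold.
#' @param conf_level confidence level for the AUC CI.
#' @return list combining [confusion_metrics()] and [auc_ci()].
#' @export
metrics_report <- function(y, scores, threshold = 0.5,
                           conf_level = 0.95) {
  cm <- confusion_metrics(y, scores, threshold)
  au <- auc_ci(y, scores, conf_level = conf_level)
  c(cm, list(auc = au$auc, auc_ci_low = au$ci_low,
             auc_ci_high = au$ci_high))
}
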