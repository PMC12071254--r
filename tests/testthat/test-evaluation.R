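test_that("confusion metrics follow the standard formulas", {
  y <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(y, y)  # perfect
  expect_equal(unlist(m[c("sensitivity", "specificity", "accuracy",
                          "f1")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 f1 = 1))
  # TP=3 FP=1 TN=4 FN=2
  y2 <- c(rep(1, 5), rep(0, 5))
  s2 <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  m2 <- confusion_metrics(y2, s2)
  expect_equal(m2$sensitivity, 0.6)
  expect_equal(m2$specificity, 0.8)
  expect_equal(m2$accuracy, 0.7)
  expect_equal(m2$f1, 2 * 0.6 * 0.75 / (0.6 + 0.75), tolerance = 1e-12)
  expect_warning(m3 <- confusion_metrics(y2, rep(0, 10)), "F1")
  expect_equal(m3$sensitivity, 0)
  expect_equal(m3$f1, 0)
  expect_error(confusion_metrics(integer(), numeric()), "empty")
})

test_that("raising the threshold never increases sensitivity", {
  set.seed(60)
  y <- rep(0:1, 30)
  s <- runif(60)
  sens <- vapply(seq(0, 1, by = 0.1), function(th) {
    suppressWarnings(confusion_metrics(y, s, th)$sensitivity)
  }, numeric(1))
  expect_true(all(diff(sens) <= 0))
})

test_that("rank AUC equals the pair-counting oracle, including ties", {
  expect_equal(auc_score(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_score(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  set.seed(61)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- rep(0:1, length.out = n)
    s <- sample(round(runif(n), 2))  # rounding forces ties
    expect_equal(auc_score(y, s), pair_count_auc(y, s))
  }
  expect_error(auc_score(rep(1, 5), rnorm(5)), "both classes")
})

test_that("AUC confidence intervals bracket the point estimate", {
  set.seed(62)
  y <- rep(0:1, each = 40)
  s <- rnorm(80) + y
  dl <- auc_ci(y, s)
  expect_true(dl$ci_low <= dl$auc && dl$auc <= dl$ci_high)
  bt <- auc_ci(y, s, method = "bootstrap", n_boot = 500, seed = 9)
  expect_true(bt$ci_low <= bt$auc && bt$auc <= bt$ci_high)
  bt2 <- auc_ci(y, s, method = "bootstrap", n_boot = 500, seed = 9)
  expect_identical(bt, bt2)  # seeded bootstrap is reproducible
})

test_that("the DeLong test is calibrated against its edge cases", {
  set.seed(63)
  y <- rep(0:1, each = 30)
  s <- rnorm(60) + 0.5 * y
  expect_equal(delong_test(y, s, s)$p_value, 1)
  expect_error(delong_test(y, s, s[1:10]), "equal length")
  # informative vs noise scores separate decisively
  y2 <- rep(0:1, each = 100)
  info <- rnorm(200) + 1.2 * y2
  noise <- rnorm(200)
  expect_lt(delong_test(y2, info, noise)$p_value, 0.01)
})

test_that("DeLong p-values agree with a sign-flip permutation oracle", {
  set.seed(64)
  for (i in 1:5) {
    n <- 120
    y <- rep(0:1, each = n / 2)
    z <- rnorm(n) + 0.8 * y
    a <- z + rnorm(n)
    b <- z + rnorm(n)
    dl <- delong_test(y, a, b)$p_value
    pp <- perm_auc_test(y, a, b, n_perm = 4000, seed = i)
    expect_lt(abs(dl - pp), 0.03)
  }
})

test_that("p-value adjustment reproduces hand-executed procedures", {
  expect_equal(adjust_pvalues(0.03, "bonferroni"), 0.03)
  expect_equal(adjust_pvalues(0.03, "benjamini_hochberg"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"),
               c(0.02, 0.8))
  # BH step-up: all equal 0.04 after monotonicity enforcement
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04),
                              "benjamini_hochberg"),
               rep(0.04, 4))
  set.seed(65)
  ps <- runif(30)
  for (meth in c("bonferroni", "benjamini_hochberg")) {
    adj <- adjust_pvalues(ps, meth)
    expect_true(all(adj >= ps & adj <= 1))
  }
  expect_error(adjust_pvalues(c(0.1, 1.4)), "0, 1")
})

test_that("the motif scan flags injected shifts with correct direction", {
  pm <- simulate_profiles(50, 50, effect_size = 0, seed = 70)
  x <- pm$x
  up <- c("TAAA", "TGGA", "TGGC", "TGGG", "TGGT")
  dn <- c("CCCA", "CCCT", "CCTC", "CCTT", "CTTT")
  cancer <- pm$labels == 1
  # inject a 3-SD shift into 10 named motifs
  for (m in up) {
    x[cancer, m] <- x[cancer, m] + 3 * sd(x[, m])
  }
  for (m in dn) {
    x[cancer, m] <- pmax(x[cancer, m] - 3 * sd(x[, m]), 0)
  }
  x <- x / rowSums(x)
  scan <- motif_scan(suppressWarnings(profile_matrix(x,
                                                     labels = pm$labels)))
  tab <- scan$table
  expect_true(all(tab$significant[tab$motif %in% up]))
  expect_true(all(tab$direction[tab$motif %in% up] == "up"))
  expect_true(all(tab$significant[tab$motif %in% dn]))
  expect_true(all(tab$direction[tab$motif %in% dn] == "down"))
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("identical groups produce no significant motifs", {
  pm <- simulate_profiles(4, 4, effect_size = 0.3, seed = 71)
  x <- rbind(pm$x[1:4, ], pm$x[1:4, ])
  rownames(x) <- paste0("s", 1:8)
  scan <- motif_scan(profile_matrix(x, labels = rep(1:0, each = 4)))
  expect_equal(scan$n_up + scan$n_down, 0L)
  expect_error(motif_scan(profile_matrix(x[1:5, ],
                                         labels = c(1, 1, 1, 0, 0))),
               "3 samples")
})
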