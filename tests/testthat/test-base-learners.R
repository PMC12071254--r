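# Base learners are exercised on a small separable fixture: a 2-SD mean
# shift on a 40-feature block of the 256 columns.
make_separable <- function(n_per_class = 30, shift = 2, seed = 40) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * 256), n, 256)
  y <- rep(1:0, each = n_per_class)
  X[y == 1, 1:40] <- X[y == 1, 1:40] + shift
  rownames(X) <- paste0("s", seq_len(n))
  colnames(X) <- all_motifs()
  list(X = X, y = y)
}

test_that("every algorithm reaches high CV AUC on separable data", {
  d <- make_separable()
  for (alg in c("lasso_logistic", "elastic_net_logistic",
                "random_forest", "gradient_boosted_trees",
                "multilayer_perceptron")) {
    tn <- tune_and_fit(d$X, d$y, learner_spec(alg, seed = 1),
                       folds = 10)
    expect_gte(tn$cv_auc, 0.95)
    p <- emdeepsd:::predict_algorithm(tn$learner, d$X)
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("tuning is deterministic and validates its inputs", {
  d <- make_separable(n_per_class = 15)
  a <- tune_and_fit(d$X, d$y,
                    learner_spec("gradient_boosted_trees", seed = 7))
  b <- tune_and_fit(d$X, d$y,
                    learner_spec("gradient_boosted_trees", seed = 7))
  expect_identical(a$params, b$params)
  expect_equal(a$cv_auc, b$cv_auc)
  expect_error(tune_and_fit(d$X, rep(1, nrow(d$X)),
                            learner_spec("lasso_logistic")),
               "single class")
  expect_error(tune_and_fit(d$X, d$y, learner_spec("random_forest"),
                            folds = 20),
               "fewer folds")
  expect_error(learner_spec("support_vector_machine"))
  expect_error(learner_spec("lasso_logistic", grid = list()), "empty")
})

test_that("stacked meta-features are out-of-fold probabilities in fixed order", {
  d <- make_separable(n_per_class = 15)
  subs <- list(SSA1 = d$X, SSA2 = d$X * 0.5 + 1, SSA3 = d$X[, 256:1])
  specs <- light_learner_specs(seed = 2)[c("lasso_logistic",
                                           "random_forest")]
  stack <- build_meta_features_train(subs, d$y, specs = specs,
                                     folds = 5, seed = 2)
  expect_equal(ncol(stack$meta), 6L)  # 3 subsequences x 2 algorithms
  expect_identical(colnames(stack$meta), stack$manifest)
  expect_identical(stack$manifest[1:2],
                   c("SSA1.lasso_logistic", "SSA1.random_forest"))
  expect_true(all(stack$meta >= 0 & stack$meta <= 1))
  # the informative stack separates out of fold
  expect_gt(auc_score(d$y, stack$meta[, "SSA1.lasso_logistic"]), 0.9)

  bad <- subs
  rownames(bad$SSA2) <- rev(rownames(bad$SSA2))
  expect_error(build_meta_features_train(bad, d$y, specs = specs,
                                         folds = 5),
               "sample order")
})

test_that("an SSA stack has 15 columns and an EMD stack 10", {
  d <- make_separable(n_per_class = 10, seed = 41)
  specs <- light_learner_specs(seed = 3)
  ssa_subs <- list(SSA1 = d$X, SSA2 = d$X, SSA3 = d$X)
  emd_subs <- list(EMD1 = d$X, EMD2 = d$X)
  s1 <- build_meta_features_train(ssa_subs, d$y, specs, folds = 5,
                                  seed = 3)
  s2 <- build_meta_features_train(emd_subs, d$y, specs, folds = 5,
                                  seed = 3)
  expect_equal(ncol(s1$meta), 15L)
  expect_equal(ncol(s2$meta), 10L)
})

test_that("under permuted labels out-of-fold AUCs stay near chance", {
  set.seed(42)
  n <- 100
  X <- matrix(rnorm(n * 256), n, 256)
  rownames(X) <- paste0("s", 1:n)
  y <- sample(rep(0:1, each = n / 2))
  specs <- light_learner_specs(seed = 4)
  stack <- build_meta_features_train(list(S = X), y, specs = specs,
                                     folds = 5, seed = 4)
  aucs <- apply(stack$meta, 2, function(p) auc_score(y, p))
  # out-of-fold estimates under the null are pessimistically biased
  # (each fold model anti-learns its own training noise), so the guard
  # that matters is the absence of optimistic leakage: no column may
  # sit clearly above chance (0.5 + ~3.4 SE at n = 50/50)
  expect_true(all(aucs < 0.7))
  expect_lt(mean(aucs), 0.6)
})

test_that("prediction-time meta-features respect the manifest", {
  d <- make_separable(n_per_class = 15, seed = 43)
  subs <- list(A = d$X, B = d$X)
  specs <- light_learner_specs(seed = 5)["lasso_logistic"]
  stack <- build_meta_features_train(subs, d$y, specs = specs,
                                     folds = 5, seed = 5)
  one <- lapply(subs, function(m) m[1, , drop = FALSE])
  p1 <- predict_meta(stack, one)
  expect_equal(dim(p1), c(1L, 2L))
  expect_identical(colnames(p1), stack$manifest)
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_error(predict_meta(stack, list(A = d$X)), "missing subsequence")

  # held-out separable data: each column individually discriminates
  d2 <- make_separable(n_per_class = 20, seed = 44)
  p2 <- predict_meta(stack, list(A = d2$X, B = d2$X))
  for (j in 1:2) expect_gte(auc_score(d2$y, p2[, j]), 0.9)
})
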