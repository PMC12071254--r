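# Machine-learning module: five learner families fitted per
# decomposition subsequence, with 10-fold cross-validated
# hyperparameter selection and out-of-fold probability meta-features
# for the downstream meta-network.

LEARNER_ALGORITHMS <- c("lasso_logistic", "elastic_net_logistic",
                        "random_forest", "gradient_boosted_trees",
                        "multilayer_perceptron")

#' Specification of one base learner
#'
#' @param algorithm one of `"lasso_logistic"`, `"elastic_net_logistic"`,
#'   `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"multilayer_perceptron"`.
#' @param grid named list of hyperparameter vectors to search (crossed);
#'   `NULL` uses the package default grid for the algorithm.
#' @param seed RNG seed for fitting.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(algorithm, grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, LEARNER_ALGORITHMS)
  grid <- grid %||% default_grid(algorithm)
  if (length(grid) == 0L) stop("empty hyperparameter grid")
  structure(list(algorithm = algorithm, grid = grid, seed = seed),
            class = "learner_spec")
}

# Default search grids. The penalty path for the penalized logistic
# models is data-driven (20 log-spaced values from glmnet), so only the
# mixing parameter appears here.
default_grid <- function(algorithm) {
  switch(algorithm,
    lasso_logistic = list(alpha = 1),
    elastic_net_logistic = list(alpha = c(0.1, 0.3, 0.5, 0.7, 0.9)),
    random_forest = list(num_trees = 500, mtry = c(8, 16, 32)),
    gradient_boosted_trees = list(max_depth = c(2, 3), nrounds = 200,
                                  eta = 0.1),
    multilayer_perceptron = list(size = c(4, 8), decay = 0.1,
                                 maxit = 100))
}

#' Default learner specifications for one decomposition stack
#'
#' @param seed base seed; each algorithm gets a distinct derived seed.
#' @param grids optional named list overriding individual default grids
#'   (e.g. smaller grids for quick runs).
#' @return named list of `learner_spec` objects, one per algorithm.
#' @export
default_learner_specs <- function(seed = 1L, grids = list()) {
  specs <- lapply(seq_along(LEARNER_ALGORITHMS), function(i) {
    alg <- LEARNER_ALGORITHMS[i]
    learner_spec(alg, grid = grids[[alg]], seed = seed + i)
  })
  names(specs) <- LEARNER_ALGORITHMS
  specs
}

#' Reduced learner specifications for quick runs
#'
#' Single-point hyperparameter grids (no search) with smaller
#' ensembles, for simulation sweeps and examples where the full grids
#' are unnecessarily expensive.
#'
#' @param seed base seed.
#' @return named list of `learner_spec` objects.
#' @export
light_learner_specs <- function(seed = 1L) {
  default_learner_specs(seed = seed, grids = list(
    elastic_net_logistic = list(alpha = 0.5),
    random_forest = list(num_trees = 200, mtry = 16),
    gradient_boosted_trees = list(max_depth = 2, nrounds = 100,
                                  eta = 0.1),
    multilayer_perceptron = list(size = 4, decay = 0.1, maxit = 50)))
}

# ---- single-algorithm fit / predict ---------------------------------

fit_algorithm <- function(algorithm, X, y, params, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.integer(y)
  model <- with_seed(seed, switch(algorithm,
    lasso_logistic = ,
    elastic_net_logistic = {
      fit <- glmnet::glmnet(X, y, family = "binomial",
                            alpha = params$alpha,
                            lambda = params$lambda_path)
      list(fit = fit, lambda = params$lambda)
    },
    random_forest = {
      ranger::ranger(x = X, y = factor(y, levels = 0:1),
                     probability = TRUE,
                     num.trees = params$num_trees,
                     mtry = min(params$mtry, ncol(X)),
                     num.threads = 1, seed = seed)
    },
    gradient_boosted_trees = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
    },
    multilayer_perceptron = {
      nnet::nnet(x = X, y = y, size = params$size,
                 decay = params$decay, maxit = params$maxit,
                 entropy = TRUE, MaxNWts = 50000, trace = FALSE)
    }))
  structure(list(algorithm = algorithm, params = params, model = model,
                 seed = seed),
            class = "base_learner")
}

# Class-1 probability predictions of a fitted base learner.
predict_algorithm <- function(learner, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  alg <- learner$algorithm
  p <- switch(alg,
    lasso_logistic = ,
    elastic_net_logistic = as.numeric(
      stats::predict(learner$model$fit, newx = X, type = "response",
                     s = learner$model$lambda)),
    random_forest = {
      pr <- stats::predict(learner$model, data = X,
                           num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    gradient_boosted_trees = as.numeric(
      stats::predict(learner$model,
                     xgboost::xgb.DMatrix(X, nthread = 1))),
    multilayer_perceptron = as.numeric(
      stats::predict(learner$model, X)))
  pmin(pmax(p, 0), 1)
}

# Expand a grid list into a list of single-combination parameter lists.
expand_param_grid <- function(grid) {
  df <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
}

# ---- cross-validated tuning -----------------------------------------

#' Tune and fit one base learner by k-fold cross-validation
#'
#' Selects the hyperparameter combination with the highest mean
#' out-of-fold AUC over a stratified k-fold split, then refits the
#' winning configuration on all samples. Deterministic given the spec's
#' seed. For the penalized logistic learners the regularization path (20
#' log-spaced values from the full data) is searched alongside the grid.
#'
#' @param X samples x features matrix (one decomposition subsequence).
#' @param y binary labels (both classes present).
#' @param spec a [learner_spec()].
#' @param folds number of CV folds (default 10; must not exceed the
#'   minority-class count).
#' @return object of class `tuned_learner`: the fitted `base_learner`
#'   plus `cv_auc` and the selected `params`.
#' @export
tune_and_fit <- function(X, y, spec, folds = 10) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  fold_id <- make_folds(y, folds, seed = spec$seed)
  combos <- expand_param_grid(spec$grid)
  if (spec$algorithm %in% c("lasso_logistic", "elastic_net_logistic")) {
    # one path fit per fold scores all 20 lambda candidates at once
    scored <- lapply(combos, function(params) {
      path <- with_seed(spec$seed,
        glmnet::glmnet(X, y, family = "binomial",
                       alpha = params$alpha, nlambda = 20)$lambda)
      oof <- matrix(NA_real_, length(y), length(path))
      for (k in sort(unique(fold_id))) {
        tr <- fold_id != k
        fit <- with_seed(spec$seed + k,
          glmnet::glmnet(X[tr, , drop = FALSE], y[tr],
                         family = "binomial", alpha = params$alpha,
                         lambda = path))
        oof[!tr, ] <- stats::predict(fit, newx = X[!tr, , drop = FALSE],
                                     type = "response", s = path)
      }
      aucs <- apply(oof, 2, function(p) auc_score(y, p))
      best_l <- which.max(aucs)
      list(params = c(params, list(lambda = path[best_l],
                                   lambda_path = path)),
           auc = aucs[best_l])
    })
    aucs <- vapply(scored, `[[`, numeric(1), "auc")
    combos <- lapply(scored, `[[`, "params")
  } else {
    aucs <- vapply(combos, function(params) {
      oof <- oof_predictions(X, y, fold_id, spec$algorithm, params,
                             spec$seed)
      auc_score(y, oof)
    }, numeric(1))
  }
  best <- combos[[which.max(aucs)]]
  fit <- fit_algorithm(spec$algorithm, X, y, best, seed = spec$seed)
  structure(list(learner = fit, params = best, cv_auc = max(aucs),
                 spec = spec, fold_id = fold_id),
            class = "tuned_learner")
}

oof_predictions <- function(X, y, fold_id, algorithm, params, seed) {
  oof <- numeric(length(y))
  for (k in sort(unique(fold_id))) {
    tr <- fold_id != k
    fit <- fit_algorithm(algorithm, X[tr, , drop = FALSE], y[tr],
                         params, seed = seed + k)
    oof[!tr] <- predict_algorithm(fit, X[!tr, , drop = FALSE])
  }
  oof
}

# ---- stacking: meta-feature construction ----------------------------

#' Out-of-fold meta-features from a learner stack
#'
#' For every (subsequence, algorithm) pair, selects hyperparameters by
#' cross-validation, then records each sample's out-of-fold predicted
#' class-1 probability (from the model trained without that sample's
#' fold) and refits the winning configuration on all samples for
#' prediction time. Columns are ordered subsequence-major,
#' algorithm-minor; the column manifest is stored with the stack so
#' prediction-time order can never drift.
#'
#' @param subsequences named list of samples x 256 matrices, all with
#'   the same row order (e.g. `SSA1`, `SSA2`, `SSA3`).
#' @param y binary labels.
#' @param specs named list of [learner_spec()]s (default: all five
#'   algorithms).
#' @param folds CV folds (default 10).
#' @param seed seed for the shared stacking fold split.
#' @return object of class `learner_stack`: `meta` (n x n_models
#'   out-of-fold probability matrix), `models` (final refits),
#'   `manifest` (column names), `fold_id`.
#' @export
build_meta_features_train <- function(subsequences, y,
                                      specs = default_learner_specs(),
                                      folds = 10, seed = 1L) {
  stopifnot(is.list(subsequences), length(subsequences) >= 1)
  n <- nrow(subsequences[[1]])
  ids <- rownames(subsequences[[1]])
  for (s in subsequences) {
    if (nrow(s) != n || !identical(rownames(s), ids)) {
      stop("subsequence matrices disagree in sample order")
    }
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  fold_id <- make_folds(y, folds, seed = seed)
  manifest <- as.vector(t(outer(names(subsequences), names(specs),
                                paste, sep = ".")))
  meta <- matrix(NA_real_, n, length(manifest),
                 dimnames = list(ids, manifest))
  models <- vector("list", length(manifest))
  names(models) <- manifest
  for (sub_name in names(subsequences)) {
    X <- as.matrix(subsequences[[sub_name]])
    for (alg in names(specs)) {
      col <- paste(sub_name, alg, sep = ".")
      tuned <- tune_and_fit(X, y, specs[[alg]], folds = folds)
      meta[, col] <- oof_predictions(X, y, fold_id,
                                     specs[[alg]]$algorithm,
                                     tuned$params, specs[[alg]]$seed)
      models[[col]] <- tuned$learner
    }
  }
  structure(list(meta = meta, models = models, manifest = manifest,
                 subsequence_names = names(subsequences),
                 fold_id = fold_id),
            class = "learner_stack")
}

#' Meta-features for new samples from a fitted stack
#'
#' Applies the full-data refits of every stacked model to new
#' subsequence matrices, in the exact column order recorded at training.
#'
#' @param stack a `learner_stack`.
#' @param subsequences named list of samples x 256 matrices covering the
#'   stack's subsequence names.
#' @return samples x n_models probability matrix.
#' @export
predict_meta <- function(stack, subsequences) {
  stopifnot(inherits(stack, "learner_stack"))
  missing <- setdiff(stack$subsequence_names, names(subsequences))
  if (length(missing)) {
    stop("missing subsequence(s): ", paste(missing, collapse = ", "))
  }
  n <- nrow(subsequences[[stack$subsequence_names[1]]])
  meta <- matrix(NA_real_, n, length(stack$manifest),
                 dimnames = list(
                   rownames(subsequences[[stack$subsequence_names[1]]]),
                   stack$manifest))
  for (col in stack$manifest) {
    sub_name <- sub("\\.[^.]+$", "", col)
    meta[, col] <- predict_algorithm(stack$models[[col]],
                                     subsequences[[sub_name]])
  }
  meta
}
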