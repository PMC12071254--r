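# Top-level modelling interface: fit an EM-DeepSSA or EM-DeepEMD
# classifier from a labeled profile matrix, with the usual fitted-model
# methods.

# Decompose every row of a profile matrix into the variant's
# subsequence matrices (SSA: SSA1-3; EMD: EMD1-2).
decompose_profiles <- function(x, variant, L = 8, pe_threshold = 0.8) {
  n <- nrow(x)
  if (variant == "ssa") {
    names_out <- c("SSA1", "SSA2", "SSA3")
    mats <- lapply(names_out, function(nm) {
      m <- matrix(0, n, 256, dimnames = dimnames(x))
      m
    })
    names(mats) <- names_out
    lambda <- matrix(0, n, L)
    for (s in seq_len(n)) {
      dec <- ssa_decompose(x[s, ], L = L)
      for (nm in names_out) mats[[nm]][s, ] <- dec$subsequences[[nm]]
      lambda[s, ] <- dec$lambda
    }
    list(subsequences = mats, lambda = lambda)
  } else {
    names_out <- c("EMD1", "EMD2")
    mats <- lapply(names_out, function(nm) {
      matrix(0, n, 256, dimnames = dimnames(x))
    })
    names(mats) <- names_out
    for (s in seq_len(n)) {
      dec <- emd_decompose(x[s, ], threshold = pe_threshold)
      for (nm in names_out) mats[[nm]][s, ] <- dec$subsequences[[nm]]
    }
    list(subsequences = mats, lambda = NULL)
  }
}

#' Fit an end-motif signal-decomposition deep-learning classifier
#'
#' Trains the full three-module pipeline on a labeled cohort of
#' end-motif profiles: (1) each 256-motif profile is decomposed by SSA
#' (window `L`, subsequences SSA1-SSA3) or EMD (PE-pooled subsequences
#' EMD1-EMD2); (2) five machine-learning base learners are tuned by
#' stratified cross-validation on every subsequence and their
#' out-of-fold class probabilities stacked into a meta-feature matrix
#' (15 models for SSA, 10 for EMD); (3) an LSTM/self-attention
#' meta-network is trained on the stacked probabilities and outputs the
#' final cancer probability.
#'
#' @param x a labeled `profile_matrix`, or a samples x 256 frequency
#'   matrix (then `y` is required).
#' @param y binary labels (1 = cancer); ignored when `x` carries labels.
#' @param variant `"ssa"` (default) or `"emd"`.
#' @param L SSA window length (default 8).
#' @param pe_threshold permutation-entropy cut for EMD pooling
#'   (default 0.8).
#' @param specs named list of [learner_spec()]s (default: the five
#'   standard algorithms).
#' @param folds cross-validation folds (default 10; needs >= 10 samples
#'   per class).
#' @param net_config a [network_config()]; by default 2 LSTM layers
#'   with 20 units for SSA and 10 for EMD, 50 epochs, Adam at 0.001.
#' @param seed master seed propagated to folds, learners and network.
#' @return object of class `em_deepsd` with `stack` (fitted base
#'   learners and out-of-fold meta-features), `network`, `fitted`
#'   (in-sample probabilities from the out-of-fold meta-features) and
#'   the decomposition settings.
#' @seealso [predict.em_deepsd()], [summary.em_deepsd()],
#'   [diversity_table()]
#' @export
em_deepsd <- function(x, y = NULL, variant = c("ssa", "emd"), L = 8,
                      pe_threshold = 0.8, specs = NULL, folds = 10,
                      net_config = NULL, seed = 1L) {
  variant <- match.arg(variant)
  if (inherits(x, "profile_matrix")) {
    y <- y %||% x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("labels are required to fit the model")
  y <- as.integer(y)
  stopifnot(length(y) == nrow(x), all(y %in% 0:1))
  if (min(table(y)) < folds) {
    stop("need at least ", folds, " samples per class for ", folds,
         "-fold cross-validation")
  }
  specs <- specs %||% default_learner_specs(seed = seed)
  dec <- decompose_profiles(x, variant, L = L,
                            pe_threshold = pe_threshold)
  stack <- build_meta_features_train(dec$subsequences, y,
                                     specs = specs, folds = folds,
                                     seed = seed)
  net_config <- net_config %||% network_config(
    hidden_units = if (variant == "ssa") 20 else 10, seed = seed)
  network <- train_network(stack$meta, y, net_config)
  fitted <- predict(network, stack$meta)
  structure(list(variant = variant, L = L,
                 pe_threshold = pe_threshold, stack = stack,
                 network = network, y = y, fitted = fitted,
                 seed = seed,
                 package_version =
                   as.character(utils::packageVersion("emdeepsd")),
                 call = match.call()),
            class = "em_deepsd")
}

#' Predict cancer probabilities for new profiles
#'
#' Applies the identical preprocessing path used in training: the same
#' decomposition parameters, the stack's full-data refits in manifest
#' order, and the network's stored normalization.
#'
#' @param object a fitted `em_deepsd` model.
#' @param newdata a `profile_matrix` or samples x 256 frequency matrix.
#' @param ... unused.
#' @return named vector of probabilities in (0, 1).
#' @export
predict.em_deepsd <- function(object, newdata, ...) {
  if (inherits(newdata, "profile_matrix")) newdata <- newdata$x
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != 256L) {
    stop("newdata must have 256 motif columns")
  }
  dec <- decompose_profiles(newdata, object$variant, L = object$L,
                            pe_threshold = object$pe_threshold)
  meta <- predict_meta(object$stack, dec$subsequences)
  p <- predict(object$network, meta)
  names(p) <- rownames(newdata)
  p
}

#' @export
print.em_deepsd <- function(x, ...) {
  cat("EM-Deep", toupper(x$variant), " model\n", sep = "")
  cat("  base learners:", length(x$stack$manifest),
      "(", paste(x$stack$subsequence_names, collapse = ", "), "x 5 )\n")
  cat("  meta-network:", x$network$config$lstm_layers, "LSTM layers x",
      x$network$config$hidden_units, "units",
      if (x$network$config$attention) "+ self-attention" else
        "(no attention)", "\n")
  cat("  training samples:", length(x$y), "(", sum(x$y == 1),
      "cancer /", sum(x$y == 0), "control )\n")
  invisible(x)
}

#' Summarize a fitted model on its training cohort
#'
#' Reports the classification metrics of the in-sample probabilities
#' (built on out-of-fold meta-features, so they are not purely
#' resubstitution estimates) at the given threshold.
#'
#' @param object a fitted `em_deepsd` model.
#' @param threshold decision threshold (default 0.5).
#' @param ... unused.
#' @return the model, invisibly; prints a metrics table.
#' @export
summary.em_deepsd <- function(object, threshold = 0.5, ...) {
  print(object)
  rep <- metrics_report(object$y, object$fitted, threshold = threshold)
  cat(sprintf(paste0("  training AUC %.3f (95%% CI %.3f-%.3f), ",
                     "SEN %.3f, SPE %.3f, ACC %.3f, F1 %.3f\n"),
              rep$auc, rep$auc_ci_low, rep$auc_ci_high,
              rep$sensitivity, rep$specificity, rep$accuracy, rep$f1))
  invisible(object)
}

#' Per-sample diversity scores and founder contributions
#'
#' The benchmark score table: for every sample, the motif diversity
#' score (MDS), the five subsequence scores, the two composites
#' (MDS-SSA, MDS-EMD), and, when a founder matrix is given, the six
#' NNLS founder contributions.
#'
#' @param pm a `profile_matrix` (or samples x 256 matrix).
#' @param founders optional 256 x 6 founder matrix.
#' @param L SSA window length.
#' @return data.frame with one row per sample: `sample_id`, 8 diversity
#'   columns and 6 founder-contribution columns when requested.
#' @export
diversity_table <- function(pm, founders = NULL, L = 8) {
  x <- if (inherits(pm, "profile_matrix")) pm$x else as.matrix(pm)
  rows <- lapply(seq_len(nrow(x)), function(s) {
    sc <- diversity_scores(x[s, ], L = L)
    if (!is.null(founders)) {
      dv <- deconvolve(x[s, ], founders)
      sc <- c(sc, dv$p)
    }
    sc
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(sample_id = rownames(x) %||%
               paste0("S", seq_len(nrow(x))),
             out, check.names = FALSE)
}

#' Save / load a fitted model bundle
#'
#' The bundle preserves everything prediction needs: the decomposition
#' settings, the base-learner refits with their column manifest, the
#' network weights and normalization statistics, and the package
#' version. Reloading and predicting on the training inputs reproduces
#' the stored probabilities.
#'
#' @param object a fitted `em_deepsd` model.
#' @param path file path (RDS).
#' @return `load_model()` returns the model; `save_model()` the path,
#'   invisibly.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "em_deepsd"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "em_deepsd")) {
    stop("file does not contain an em_deepsd model")
  }
  now <- as.character(utils::packageVersion("emdeepsd"))
  if (!identical(object$package_version, now)) {
    warning("model was fitted with package version ",
            object$package_version, ", current is ", now)
  }
  object
}
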