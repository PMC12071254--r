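# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG state
#'
#' Runs `expr` with `set.seed(seed)` in effect and restores the caller's
#' RNG state afterwards, so seeded internals never perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Stratified k-fold assignment; returns an integer vector of fold ids in 1..k.
make_folds <- function(y, k, seed = NULL) {
  y <- as.integer(y)
  stopifnot(k >= 2)
  if (min(table(y)) < k) {
    stop("fewer samples in the minority class (", min(table(y)),
         ") than folds (", k, "); use fewer folds")
  }
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Numerically stable sigmoid.
sigmoid <- function(x) 1 / (1 + exp(-x))

`%||%` <- function(a, b) if (is.null(a)) b else a
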