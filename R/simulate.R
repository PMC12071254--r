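# Synthetic end-motif data with the cancer-associated shift reported for
# plasma cfDNA: thymine-prefixed motifs up, cytosine-prefixed motifs
# down in cancer. Used throughout the tests so that no controlled-access
# sequencing data are required.

# Deterministic control baseline: a smooth, peaky 256-motif frequency
# vector. Healthy plasma cfDNA is dominated by cytosine-prefixed end
# motifs (CCNN-type cleavage preference), so the first position is
# C-heavy; a smooth oscillation over the lexicographic index creates
# the peak/trough texture that makes the decompositions informative.
# With this shape, the cancer shift (T up, C down) flattens the
# distribution, so cancer samples score a higher motif diversity.
baseline_profile <- function() {
  motifs <- all_motifs()
  first_w <- c(A = 0.24, C = 0.36, G = 0.19, T = 0.21)
  rest_w <- c(A = 0.28, C = 0.24, G = 0.21, T = 0.27)
  pos_w <- matrix(0, 256, 4)
  pos_w[, 1] <- log(first_w[substr(motifs, 1, 1)])
  for (k in 2:4) {
    pos_w[, k] <- log(rest_w[substr(motifs, k, k)])
  }
  i <- seq_len(256)
  logp <- rowSums(pos_w) + 0.35 * sin(2 * pi * i / 16) +
    0.15 * cos(2 * pi * i / 64)
  p <- exp(logp)
  p / sum(p)
}

default_up_motifs <- function() {
  motifs <- all_motifs()
  unique(c("TAAA", "TGGA", "TGGC", "TGGG", "TGGT",
           motifs[startsWith(motifs, "T")]))
}

default_down_motifs <- function() {
  motifs <- all_motifs()
  unique(c("CCCA", "CCCT", "CCTC", "CCTT", "CTTT",
           motifs[startsWith(motifs, "C")]))
}

#' Simulate labeled end-motif profile matrices
#'
#' Draws control samples around a fixed smooth baseline profile and
#' cancer samples around the same baseline with `up_motifs` multiplied
#' by `exp(effect_size)` and `down_motifs` by `exp(-effect_size)`
#' (renormalized). Sample-level variation is logistic-normal: Gaussian
#' noise with standard deviation `dispersion` on the log-frequencies,
#' then renormalization, so every row sums to 1 exactly. At
#' `effect_size = 0` the two groups are exchangeable.
#'
#' @param n_cancer,n_control samples per group.
#' @param effect_size log-scale shift applied to the motif classes
#'   (default 0.5).
#' @param dispersion SD of the per-motif log-frequency noise
#'   (default 0.15).
#' @param up_motifs,down_motifs motif sets shifted up/down in cancer;
#'   defaults are the thymine-prefixed and cytosine-prefixed classes.
#' @param seed RNG seed.
#' @return labeled `profile_matrix` (cancer rows first, `label` 1).
#' @export
simulate_profiles <- function(n_cancer = 50, n_control = 50,
                              effect_size = 0.5, dispersion = 0.15,
                              up_motifs = default_up_motifs(),
                              down_motifs = default_down_motifs(),
                              seed = 1L) {
  stopifnot(n_cancer >= 1, n_control >= 1, effect_size >= 0,
            dispersion >= 0)
  if (effect_size > 0 &&
      (length(up_motifs) == 0 || length(down_motifs) == 0)) {
    stop("empty motif sets with a non-zero effect size")
  }
  motifs <- all_motifs()
  base <- baseline_profile()
  shift <- numeric(256)
  shift[motifs %in% up_motifs] <- effect_size
  shift[motifs %in% down_motifs] <- -effect_size
  cancer_base <- base * exp(shift)
  cancer_base <- cancer_base / sum(cancer_base)
  draw <- function(center, n) {
    logc <- log(center)
    t(vapply(seq_len(n), function(i) {
      p <- exp(logc + stats::rnorm(256, 0, dispersion))
      p / sum(p)
    }, numeric(256)))
  }
  with_seed(seed, {
    xc <- draw(cancer_base, n_cancer)
    x0 <- draw(base, n_control)
    x <- rbind(xc, x0)
    rownames(x) <- c(sprintf("cancer_%03d", seq_len(n_cancer)),
                     sprintf("control_%03d", seq_len(n_control)))
    colnames(x) <- motifs
    profile_matrix(x, labels = rep(1:0, c(n_cancer, n_control)))
  })
}

#' Simulate a toy reference genome and fragment BED for the extractor
#'
#' Plants `n_fragments` fragments on a synthetic chromosome so that the
#' extracted end-motif distribution converges to `target_profile`: each
#' fragment's Watson-end 4-mer and Crick-end 4-mer are drawn
#' independently from the target and written into the reference at the
#' fragment boundaries.
#'
#' @param target_profile 256 motif frequencies.
#' @param n_fragments number of fragments (>= 1).
#' @param fragment_length span of each planted fragment in bp
#'   (default 20).
#' @param seed RNG seed.
#' @return list with `reference` (named character, one chromosome),
#'   `fragments` (BED-style data.frame), and writer helpers are left to
#'   the caller ([write_simulated_fragments()]).
#' @export
simulate_fragments <- function(target_profile, n_fragments,
                               fragment_length = 20, seed = 1L) {
  if (inherits(target_profile, "end_motif_profile")) {
    target_profile <- target_profile$frequencies
  }
  stopifnot(length(target_profile) == 256L, all(target_profile >= 0),
            fragment_length >= 8)
  if (n_fragments < 1) stop("n_fragments must be >= 1")
  motifs <- all_motifs()
  gap <- 10L
  with_seed(seed, {
    watson <- sample(motifs, n_fragments, replace = TRUE,
                     prob = target_profile)
    crick <- sample(motifs, n_fragments, replace = TRUE,
                    prob = target_profile)
    unit <- fragment_length + gap
    total <- n_fragments * unit + gap
    seq_chars <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    starts <- gap + (seq_len(n_fragments) - 1L) * unit  # 0-based
    for (k in seq_len(n_fragments)) {
      s <- starts[k]
      seq_chars[(s + 1):(s + 4)] <- strsplit(watson[k], "")[[1]]
      e <- s + fragment_length
      seq_chars[(e - 3):e] <- strsplit(revcomp(crick[k]), "")[[1]]
    }
    ref <- paste(seq_chars, collapse = "")
    names(ref) <- "chrSim"
    list(reference = ref,
         fragments = data.frame(chrom = "chrSim", start = starts,
                                end = starts + fragment_length))
  })
}

#' Write a simulated reference/fragment pair to FASTA and BED
#'
#' @param sim result of [simulate_fragments()].
#' @param fasta_path,bed_path output paths.
#' @return invisibly, the two paths.
#' @export
write_simulated_fragments <- function(sim, fasta_path, bed_path) {
  writeLines(c(paste0(">", names(sim$reference)), sim$reference),
             fasta_path)
  utils::write.table(sim$fragments, bed_path, sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(c(fasta_path, bed_path))
}

#' Synthetic founder-profile matrix
#'
#' Builds a 256 x 6 non-negative matrix of linearly independent columns,
#' each summing to 1, as a stand-in for a user-supplied founder
#' ("F-profile") matrix. Each column is the smooth baseline modulated by
#' a distinct oscillation plus seeded noise. This is a synthetic
#' fixture; real founder profiles are an external input.
#'
#' @param seed RNG seed.
#' @return 256 x 6 matrix with motif rownames and colnames `F1..F6`.
#' @export
make_founder_fixture <- function(seed = 1L) {
  motifs <- all_motifs()
  base <- baseline_profile()
  i <- seq_len(256)
  with_seed(seed, {
    F <- vapply(1:6, function(k) {
      logp <- log(base) + 0.4 * sin(2 * pi * k * i / 256) +
        stats::rnorm(256, 0, 0.2)
      p <- exp(logp)
      p / sum(p)
    }, numeric(256))
    rownames(F) <- motifs
    colnames(F) <- paste0("F", 1:6)
    F
  })
}
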