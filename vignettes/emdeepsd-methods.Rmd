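---
title: "End-motif signal decomposition for cfDNA cancer classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-motif signal decomposition for cfDNA cancer classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emdeepsd)
```

## The problem

Plasma cell-free DNA (cfDNA) is fragmented non-randomly: the 4-mer of
reference sequence at each fragment's 5' end (the *end motif*) carries a
signature of the nuclease milieu and chromatin state of the tissue of
origin. Cancer patients show a reproducible tilt in these motif
preferences — thymine-prefixed motifs gain frequency and
cytosine-prefixed motifs lose it — so the 256-dimensional end-motif
frequency profile of a plasma sample is a practical, cheap biomarker for
cancer detection.

Summaries of the whole profile, such as the motif diversity score (the
normalized Shannon entropy of the 256 frequencies), compress the signal
into one number and discard most of its structure. This package instead
treats the lexicographically ordered profile as a 256-point series and
decomposes it into subsequences of distinct character before modelling:
a trend component, a local peak/trough component, and fine-grained
fluctuation components. Each subsequence is modelled separately by a
panel of machine-learning classifiers, and a small recurrent
meta-network fuses the panel's probabilities into the final cancer
probability. The package implements the full stack: extraction,
decomposition, diversity scores, founder-profile deconvolution, the
stacked learners, the meta-network, evaluation statistics, and a
synthetic-data generator used for validation.

## End-motif extraction

Fragments enter as BED spans or as proper, correctly oriented BAM pairs
(one fragment per pair, taken from the forward mate), filtered to insert
sizes of at most 600 bp and, for BAM, mapping quality at least 20.
Coordinates are 0-based half-open throughout. The Watson-strand motif is
the reference 4-mer at the left fragment end; the Crick-strand motif is
the reverse complement of the reference 4-mer ending at the right end,
i.e. the 4-mer read 5'-to-3' on the minus strand. Both motifs are taken
from the reference genome, not from read bases, so sequencing errors do
not contaminate the profile. Every retained fragment contributes exactly
two counts. Windows that fall off the chromosome or contain non-ACGT
reference bases skip the fragment end (with a counter) rather than
failing the sample: a handful of N-context fragments should never
invalidate a library. Fragments shorter than 8 bp would have overlapping
end windows; both ends are still counted, since the two strands' motifs
remain distinct measurements.

## Signal decomposition

**Singular spectrum analysis (SSA).** The profile `x` (N = 256) is
embedded into the L x K Hankel trajectory matrix (window L = 8 by
default, K = N − L + 1), decomposed by SVD, and the elementary
components are grouped by index — {1}, {2,3}, {4..8} — and
anti-diagonally averaged back into three length-256 subsequences. SSA1
(the leading component) carries the global trend of the profile, SSA2
captures local peaks and troughs, and SSA3 collects the remaining
fine-scale fluctuation. Because the groups partition all L components,
SSA1+SSA2+SSA3 reconstructs the input to machine precision; this
completeness is asserted in the tests rather than assumed. The
eigenvalues of the lag-covariance matrix are kept with the
decomposition: their group shares later serve as the weights of the
composite diversity score. Window length matters only weakly (L between
8 and 128 gives similar downstream classifiers); L = 8 keeps the
trajectory matrix cheap and the three groups interpretable.

**Empirical mode decomposition (EMD).** The profile is sifted into
intrinsic mode functions: at each step, natural cubic splines through
the local maxima and minima define upper and lower envelopes, and the
envelope mean is subtracted until the candidate satisfies the IMF
criteria (zero-crossing and extrema counts equal or differing by one,
envelope mean locally negligible). Extraction stops when the residual is
monotone (fewer than two interior maxima or minima) or negligible in
amplitude. Numerical choices the sifting requires but the textbook
definition leaves open: envelopes are anchored by mirror-extending two
extrema beyond each boundary (untreated ends visibly corrupt the first
and last 10-20 points of every IMF); the envelope-mean tolerance is
|E| < 0.05 x local amplitude with a relative-change (Cauchy) fallback
and a hard cap of 100 sifting iterations. The residual is always
maintained as `series − sum(IMFs)`, so additive reconstruction is exact
by construction.

Since different samples yield different numbers of IMFs, the IMFs are
pooled into exactly two subsequences by permutation entropy (PE):
EMD1 sums IMFs with PE >= 0.8 (fast, noise-like modes) and EMD2 sums
the rest plus the residual (the trend; the residual is always a trend
term, so it always joins the low-PE pool). PE is computed over ordinal
patterns of order m = 4 at delay 1, normalized by log(4!): with 24
possible patterns and 253 windows in a 256-point series, the pattern
distribution is well estimated and the 0.8 threshold sits in a stable
region — monotone series score 0, i.i.d. noise scores above 0.99. Ties
within a window are broken by index order, which makes PE of constant
series 0 rather than undefined.

## Diversity scores and founder deconvolution

The motif diversity score of a frequency vector is
`MDS = sum(-p_i log p_i) / log 256`, in [0, 1], with `0 log 0 := 0`.
Decomposition subsequences contain negative values, so each subsequence
is first softmax-normalized (computed with max-subtraction; exactly
shift-invariant) and then scored with the same entropy:
`MDS_Sub = mds(softmax(q))`. Five subsequence scores result (SSA1-3,
EMD1-2), plus two composites: MDS-SSA, the eigenvalue-share-weighted
mean of the three SSA scores, and MDS-EMD, the plain mean of the two
EMD scores. The log base cancels in the ratio, so natural logs are
used.

A complementary benchmark expresses each profile as a non-negative
mixture of six "founder" end-motif profiles; the weights are estimated
by non-negative least squares (Lawson-Hanson, via `pracma::lsqnonneg`)
and reported both raw and as percentages of their sum — the literature
speaks of percentage contributions, but the mixture model itself is
un-normalized, so both views are kept. The package ships only a
synthetic founder fixture (`make_founder_fixture()`, full-rank,
column-stochastic); real founder profiles are an external input the
user supplies.

## The stacked learner module

Every subsequence matrix (samples x 256) is modelled by five families:
LASSO logistic regression, elastic-net logistic regression, random
forest, gradient-boosted trees, and a single-hidden-layer perceptron
(glmnet, ranger, xgboost, nnet). Hyperparameters are selected by
stratified 10-fold cross-validated AUC; the winning configuration is
refit on all samples. The meta-feature each model contributes is its
*out-of-fold* class-1 probability — each sample's value comes from the
model trained without that sample's fold — so the meta-network never
sees resubstitution probabilities, the defensible reading of a stacking
protocol whose leakage control is otherwise unstated. The column order
(subsequence-major, algorithm-minor: 15 columns for SSA, 10 for EMD) is
recorded as a manifest and enforced at prediction time.

Default grids: lasso/elastic-net over a 20-value log-spaced penalty
path (mixing 0.1-0.9 for the elastic net); forests of 500 trees with
mtry in {8, 16, 32}; boosting depth {2, 3} at 200 rounds, learning rate
0.1; perceptron sizes {4, 8} with weight decay 0.1. The perceptron grid
is deliberately small: nnet optimizes all weights by quasi-Newton
steps, whose cost grows sharply with hidden-layer width on 256-input
data, while CV AUC on end-motif subsequences saturates by 4-8 hidden
units; weight decay plays the regularizing role that early stopping
would otherwise play. `light_learner_specs()` provides single-point
grids with smaller ensembles for simulation sweeps.

## The meta-network

The stacked probabilities of one sample are treated as a sequence of
n_models one-dimensional timesteps in manifest order and passed through
two LSTM layers (20 hidden units for the SSA stack, 10 for the EMD
stack), a self-attention layer
(`softmax(Q K' / sqrt(d_k)) V`, with Q, K, V three learned linear maps
of the LSTM output and d_k the hidden size), global average pooling
over timesteps, and a sigmoid dense head. Training minimizes binary
cross-entropy (the loss a sigmoid output implies) with Adam at learning
rate 0.001 for 50 epochs in batches of 64, a final partial batch
allowed. Meta-features are z-scored with statistics frozen from the
training set. Forward pass, analytic backpropagation and Adam are
implemented directly on base-R matrices; the gradients are verified
against central-difference numerical differentiation in the test suite,
and training is bit-reproducible given the seed (weight initialisation
and batch shuffling are the only random elements). Setting
`attention = FALSE` in `network_config()` removes exactly the attention
layer (pooling then acts on the LSTM output), which supports ablation
comparisons structurally.

## Evaluation

Sensitivity, specificity, accuracy and F1 come from the thresholded
confusion matrix; F1 is defined as 0 (with a warning) when precision or
sensitivity is undefined. AUC is the rank-based Mann-Whitney estimator
with 0.5 tie credit — exactly the normalized count of concordant pairs,
asserted against an O(n^2) oracle in the tests. Confidence intervals
use the DeLong variance (or a seeded percentile bootstrap), and paired
model comparisons use DeLong's test for correlated AUCs, both via pROC;
identical score vectors are a defined edge case with p = 1. The
per-motif differential scan applies a two-sided Wilcoxon rank-sum test
to each motif (normal approximation with continuity correction at group
sizes >= 10, exact enumeration below), directions by median difference,
with Bonferroni (default) or Benjamini-Hochberg adjustment across the
256 tests.

## The synthetic-data generator

Because the cohorts behind the published end-motif studies are
controlled-access, the package validates itself on synthetic profiles.
Controls are drawn around a fixed smooth baseline (per-position base
preferences favouring A/T starts, modulated by a smooth oscillation
over the lexicographic index so the profile has the peak/trough texture
real profiles show); cancer samples use the same baseline with
thymine-prefixed motifs multiplied by `exp(effect_size)` and
cytosine-prefixed motifs by `exp(-effect_size)`, renormalized. The
motif sets default to the full T- and C-prefixed classes, which contain
the top differential motifs reported for real cohorts (TAAA, TGGA,
TGGC, TGGG, TGGT up; CCCA, CCCT, CCTC, CCTT, CTTT down). Sample-level
noise is logistic-normal — Gaussian with SD `dispersion` (default 0.15)
on log-frequencies, then renormalization — chosen over a Dirichlet so
per-motif dispersion is tunable independently of the mean. At
`effect_size = 0` the groups are exchangeable by construction, which is
what the null-calibration tests rely on.

What the generator does *not* emulate: between-sample sequencing-depth
variation (profiles are continuous frequencies, not multinomial
counts), batch effects between sequencing modalities, correlated noise
across related motifs, and biological heterogeneity within the cancer
class. Passing the end-to-end tests therefore shows that the pipeline
recovers a planted, well-behaved class difference and stays calibrated
under a true null — not that it attains any particular accuracy on
real cfDNA cohorts.

A small fragment-level generator (`simulate_fragments()`) plants
Watson/Crick end motifs drawn from a target distribution into a
synthetic reference and BED, so the extractor can be validated against
a known generating distribution without any genome download.

## Problem sizes used in the validation suite

The package's simulation studies run at: training 60 cancer / 60
control, held-out 20 / 20, effect 0.5 and null, with the full default
grids for the headline run; the effect-size monotonicity sweep
(effects 0, 0.1, 0.25, 0.5, five seeds each) and the null run use
`light_learner_specs()` with a 30-epoch network, which leaves the
generator conditions untouched and only shrinks the hyperparameter
search. Reconstruction, NNLS and AUC oracle checks use 50-100 random
systems each. These sizes were chosen as the smallest at which the
quantities of interest are stable; all are fixed in code.

## Known limitations

* EMD has no uniqueness theory; different envelope/stopping conventions
  yield slightly different IMFs. The PE pooling into two subsequences
  deliberately blunts this sensitivity, and only the pooled E1/E2 feed
  the models.
* The meta-network treats base-learner probabilities as an ordered
  sequence; the order is a recorded convention (manifest), not a
  physical time axis, and a different order would train a slightly
  different network. Prediction with shuffled columns is rejected, never
  silently reordered.
* nnet's optimizer limits the practical perceptron width; with many
  more samples or features a different MLP engine would be worth the
  dependency.
* `wilcox.test`'s normal approximation at group sizes just above 10 is
  slightly conservative with heavy ties; end-motif frequencies are
  continuous, so ties are rare.
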