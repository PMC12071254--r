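# emdeepsd

Cancer-versus-control classification from plasma cell-free DNA (cfDNA)
**end-motif profiles** — the frequency vector of the 256 possible 4-mers
of reference sequence found at cfDNA fragments' 5' ends. Cancer shifts
these preferences (thymine-prefixed motifs up, cytosine-prefixed motifs
down), and this package implements a signal-decomposition deep-learning
framework that exploits the *structure* of the 256-point profile rather
than one-number summaries of it.

The package is for computational biologists working on cfDNA
fragmentomics: it takes aligned fragments (BAM/BED) plus a reference
FASTA, or precomputed profile matrices (TSV), and provides both the
classical benchmarks (motif diversity score, founder-profile
deconvolution) and the full decomposition/stacking/deep-learning
pipeline, with the evaluation statistics used in this literature.

## The method

Each sample's lexicographically ordered profile `x ∈ Δ^255` is treated
as a 256-point series and decomposed two ways:

* **SSA** — embed into the Hankel trajectory matrix (window L = 8), SVD,
  group components {1}, {2,3}, {4..8}, diagonal-average back to three
  subsequences `SSA1 + SSA2 + SSA3 = x` (trend, local peaks/troughs,
  fine fluctuations);
* **EMD** — sift into intrinsic mode functions plus residual, then pool
  by permutation entropy into `EMD1` (PE ≥ 0.8, noise-like) and `EMD2`
  (PE < 0.8 plus residual, trend), with `EMD1 + EMD2 = x`.

Two model families build on the subsequences:

* **Decomposition diversity scores** (MDS-SDs). With
  `MDS(p) = Σᵢ −pᵢ log pᵢ / log 256`, each subsequence `q` is scored as
  `MDS_Sub(q) = MDS(softmax(q))`; composites are MDS-SSA (eigenvalue-
  share-weighted mean of the three SSA scores) and MDS-EMD (mean of the
  two EMD scores). Founder deconvolution solves
  `min_{p ≥ 0} ‖x − F p‖₂` over a 256×6 founder matrix by NNLS.
* **EM-DeepSSA / EM-DeepEMD.** Five learners (LASSO, elastic net,
  random forest, gradient boosting, MLP) are tuned by stratified
  10-fold CV on every subsequence; their out-of-fold class
  probabilities (15 columns for SSA, 10 for EMD) feed a meta-network:
  two LSTM layers (20/10 units), self-attention
  `softmax(QKᵀ/√d_k)V`, global average pooling, sigmoid head, trained
  with Adam (50 epochs, lr 0.001, batch 64). The forward/backward pass
  is implemented in base R and verified against numerical gradients.

## Worked example

```r
library(emdeepsd)

# simulate a labeled cohort with the cancer-associated motif shift
train <- simulate_profiles(n_cancer = 60, n_control = 60,
                           effect_size = 0.5, seed = 11)
test  <- simulate_profiles(n_cancer = 20, n_control = 20,
                           effect_size = 0.5, seed = 12)

fit <- em_deepsd(train, variant = "ssa", seed = 42)
print(fit)
#> EM-DeepSSA model
#>   base learners: 15 ( SSA1, SSA2, SSA3 x 5 )
#>   meta-network: 2 LSTM layers x 20 units + self-attention
#>   training samples: 120 ( 60 cancer / 60 control )

p <- predict(fit, test)
auc_score(test$labels, p)
#> [1] 1
```

The model recovers the planted class difference perfectly on this
strongly shifted synthetic cohort (held-out AUC 1.0 over 40 test
samples); weaker effects give intermediate AUCs and a zero effect stays
at chance (see the test suite). The benchmark scores behave as expected
— cancer samples are more diverse:

```r
m <- apply(train$x, 1, mds)
tapply(m, train$labels, mean)
#>         0         1
#> 0.9785857 0.9798151

scan <- motif_scan(train)
print(scan)
#> Motif scan (bonferroni, alpha = 0.05): 64 up, 64 down of 256 motifs
```

The cancer group's mean MDS is higher (its motif usage is more
uniform), and the scan recovers the planted shift: the 64
thymine-prefixed motifs up and the 64 cytosine-prefixed motifs down.

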