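# hicdecon

Reference-free estimation of cell-type proportions and cell-type-specific
chromatin contact profiles from bulk Hi-C data.

Bulk Hi-C measures chromatin contacts averaged over the cell types present in
a tissue sample, so differences in cell-type composition across samples
confound downstream analyses (differential contact testing, interactome QTL
mapping) exactly as they do in bulk expression and methylation studies.  For
Hi-C, no reference contact profiles per cell type exist yet, so the
deconvolution must be unsupervised.  `hicdecon` implements a two-step
non-negative matrix factorization estimator for this problem, together with a
single-cell-Hi-C-based mixture simulator with known ground truth, evaluation
metrics that handle the cluster-label permutation ambiguity, and post-hoc
annotation of the inferred contact profiles.

## The estimator

Let **V** be the *p* × *n* non-negative mixture matrix: one row per bin-pair
(a pair of fixed-width genomic bins, intra- or interchromosomal), one column
per bulk sample, entries CPM-normalized contact counts.  For a chosen number
of cell types *k*:

1. **Step 1 — initial factorization.** V ≈ W₁H₁ by multiplicative-update NMF
   under the Euclidean loss ‖V − WH‖², from random initializations, keeping
   the best of many restarts.
2. **Feature selection.** From the fitted profile matrix W₁, with
   p(i,j) = W₁(i,j)/Σⱼ W₁(i,j):
   - feature score FSᵢ = 1 + (1/log₂k) Σⱼ p(i,j) log₂ p(i,j) — one minus the
     normalized profile entropy, 1 for a fully cell-type-specific bin-pair;
   - across-cell-type SD, SDᵢ = sample SD of W₁(i,·).

   An intrachromosomal bin-pair is informative when
   FSᵢ > median(FS) + 3·median|FS − median(FS)|; an interchromosomal bin-pair
   when SDᵢ > mean(SD) + 3·sd(SD).  (The benchmark alternatives — no
   selection, top-N Fano factor, and the mean/median threshold variants — are
   available by name.)
3. **Step 2 — final factorization.** NMF of the reduced matrix V* (the
   informative rows) gives W* and H*; the columns of H* are normalized to sum
   to one and reported as cell-type proportions.  Goodness of fit is
   PVE = 1 − RSS/Σ V*², which also drives model selection over bin size and
   *k* (`hicdecon_grid`).

Alternative Hi-C readouts (Crane-style normalized insulation scores,
A/B-compartment PC scores, absolute-value transformed) can be deconvolved
with the same machinery.

## Worked example

Simulate the three-cell-line benchmark (12 bulk samples — 3 pure, 9 mixed —
assembled from synthetic single cells with realistic depth variation,
distance decay, and cell-to-cell decay heterogeneity), deconvolve it, and
score the estimate against the realized truth:

```r
library(hicdecon)

study <- simulate_mixture_study("three_type", seed = 1)
fit <- hicdecon(study$bulk, k = 3, restarts = 20, seed = 1)
fit
#> two-step Hi-C deconvolution: k = 3 cell types, 12 samples
#>   informative bin-pairs: 136 of 1830 (strategy: two_step)
#>   proportion of variance explained (V*): 0.9997

evaluate_proportions(coef(fit), study$truth)
#> deconvolution accuracy: MAD 0.0272, Pearson r 0.9968
#> cluster -> truth matching: 3 1 2

round(coef(fit)[, 1:4], 3)
#>          pure1 pure2 pure3  mix1
#> cluster1 0.045 0.939 0.012 0.274
#> cluster2 0.056 0.047 0.987 0.651
#> cluster3 0.899 0.014 0.001 0.075
```

The selection step kept 136 of 1830 bin-pairs; the estimated proportions
deviate from the realized mixing truth by 0.027 on average (clusters are
matched to truth by optimal assignment before scoring, since NMF returns
them in arbitrary order).  The pure samples are recognized as nearly
one-hot columns.

A thin command-line wrapper over the same functions is installed at
`inst/cli/hicdecon.R` (subcommands `run`, `gridsearch`, `simulate`,
`evaluate`).

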