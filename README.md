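# crcseg

Two-stage computer-aided diagnosis for colorectal cancer histopathology,
in R:

1. **Multi-class tissue segmentation.** A U-Net style convolutional
   network segments H&E image tiles into 14 tissue compartments (normal
   glands, low-grade dysplasia, high-grade dysplasia/tumor, submucosal
   stroma, desmoplastic stroma, lamina propria, mucus, necrosis/debris,
   lymphocytes, erythrocytes, adipose tissue, muscle, nerve, background).
   The network can be trained under four interchangeable objectives —
   categorical cross-entropy, focal loss, bi-tempered logistic loss, and
   the Lovász-softmax surrogate of the Jaccard index — so their effect on
   segmentation quality can be compared under an otherwise identical
   protocol.
2. **Slide-level risk classification.** A 1000-tree random forest turns
   slide segmentation maps into one of four ordinal risk categories
   (`other < hyperplasia < low_grade_dysplasia < high_risk`) using 18
   interpretable features per tissue fragment: the normalized 14-bin
   class histogram plus count and mean/min/max area (µm²) of tumor
   clusters after a 30 µm² filter. Slides are labelled by their
   worst-graded fragment.

The whole pipeline — network, backpropagation, Adam, the four losses with
analytic gradients, tiled whole-slide inference, evaluation metrics, and
the classifier — is implemented in R (vectorized linear algebra over
BLAS; no deep-learning framework). A synthetic-data module generates
tissue-like textured tiles with paired masks and labelled slide cohorts,
so everything trains and tests offline.

## The core quantities

For pixel-wise class probabilities ŷ and one-hot targets y over C = 14
classes:

* cross-entropy: `L = -Σ_i y_i log ŷ_i`
* focal: `L = -Σ_i α (1-ŷ_i)^γ y_i log ŷ_i` (α = 0.25, γ = 2)
* bi-tempered: `L = Σ_i [ y_i (log_t1 y_i - log_t1 ŷ_i) -
  (y_i^(2-t1) - ŷ_i^(2-t1)) / (2-t1) ]` with ŷ from the tempered softmax
  `ŷ_i = exp_t2(â_i - λ(â))`, `Σ ŷ_i = 1` (t1 = 0.8, t2 = 1.2)
* Lovász-softmax: `L = (1/|C|) Σ_c Δ̄_Jc(m(c))`, the Lovász extension of
  the per-class Jaccard loss applied to the error vector m(c)

Evaluation uses per-class and mean Dice `2|P∩R| / (|P|+|R|)`, benchmark
F1 after class merging (with optional relabeling of near-white lumina,
mean RGB > 240, as background), the paired Wilcoxon signed-rank test,
one-vs-all ROC/AUC, and quadratic weighted kappa
`κ = 1 - Σ w_ij O_ij / Σ w_ij E_ij`, `w_ij = (i-j)² / (K-1)²`.

## Worked example

```r
library(crcseg)

# train the segmentation network on synthetic tissue under the
# Lovász-softmax loss (scaled-down protocol; ~2-3 min on one CPU)
bench <- segmentation_benchmark(loss_config("lovasz_softmax"), seed = 1)
bench$test_dice
#> [1] 0.8869
max(tidy(bench$fit)$val_dice)   # best validation Dice over the 20 epochs
#> [1] 0.9017

# slide-level risk classification on a synthetic 160-slide cohort
cases <- generate_cohort(
  cohort_spec(n_slides = setNames(rep(40, 4), risk_levels())), seed = 2)
fit <- fit_forest(cases, n_trees = 1000, folds = 5, seed = 3)
glance(fit)[, c("kappa", "accuracy", "auc_high_risk")]
#> # A tibble: 1 × 3
#>   kappa accuracy auc_high_risk
#>   <dbl>    <dbl>         <dbl>
#> 1     1        1             1
```

`bench$test_dice` is the mean Dice over tissue classes on 20 held-out
synthetic tiles — 0.89 means the network recovers the class geometry
almost everywhere (the synthetic task is separable by construction; see
the methods vignette for what this does and does not demonstrate).
`kappa` is the out-of-fold quadratic weighted kappa of slide-level risk
labels; the synthetic cohort encodes each category's defining features
explicitly, so near-perfect recovery is the expected behavior of a
correct pipeline, with most residual confusion between hyperplasia and
low-grade dysplasia (their histograms overlap by design).

A thin command-line wrapper is installed with the package
(`inst/cli/crcseg`): `simulate tiles|cohort`, `evaluate` (Dice or
benchmark F1 with `--benchmark crag|glas` and `--lumen keep|remove`), and
`model describe`.

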