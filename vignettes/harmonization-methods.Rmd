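---
title: "Uniformly shaped harmonization: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uniformly shaped harmonization: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shambhala)
```

## The harmonization model

Cross-platform comparison of bulk expression profiles is obstructed by
platform effects: each instrument has its own response curve (microarray
intensities saturate; sequencing counts are linear on the log scale up to
shot noise), its own dynamic range, and gene-specific biases (probe
affinity, mappability). Flexible-output normalizers recompute their result
from the whole sample set, so adding one sample changes every previously
normalized value. The harmonizer implemented here instead maps **each
profile independently** into a fixed universal shape defined by two
auxiliary datasets:

1. **Merge & quantile-normalize.** The raw profile joins the calibration
   dataset P as one extra column with weight 1 and the merged matrix is
   quantile-normalized (`quantile_normalize()`, delegating to
   `limma::normalizeQuantiles` with tie-averaging), producing P′. Because
   quantile normalization replaces each sample's empirical distribution by
   the common reference, any monotone warp of a sample's measurement scale
   — the removable part of a platform effect — is eliminated here. P's
   gene list contains only strongly expressed genes, so intersecting with
   it doubles as an expression filter; low-expressed genes, whose
   measurements are least reliable, never reach the output.
2. **Transform into the shape of Q.** P′ is mapped toward the reference
   definitive dataset Q by one of two block transforms (below), giving P″.
   Q is held fixed: it *defines* the universal format, and its samples are
   never modified.
3. **Extract & rescale.** The transformed column of the original sample is
   extracted; after all samples are processed, the assembled matrix is
   rescaled per gene (PBR/QBR/RBR; below).

### The block-linear transform (method `shambhala1`)

Genes are clustered into K groups and samples into L groups by k-means on
per-gene standardized data of the combined set (P′ and Q together). Within
each dataset the model

$$x_{gi} \approx A_{\alpha(g),\beta(i)}\, b_g + c_g + \sigma_g\,
\varepsilon_{gi}$$

is fitted by iterated least squares (block effects A given gene
coefficients b, c; then per-gene regressions given A), on per-gene,
per-dataset standardized values. The model is only identified up to a
scale exchange between A and b, so after each sweep b is normalized to
unit mean square within every gene cluster (sign fixed so that the cluster
mean of b is non-negative) and the scale is absorbed into A. With both
datasets expressed in the same gauge, the dataset-specific parameters are
replaced by their sample-size-weighted averages and P′ is reconstructed
under the shared parameters, keeping its standardized residuals. Averaging
over `n_repeats` random clustering restarts smooths the dependence on any
single k-means solution. Defaults: K = 25, L = 5, 30 restarts, 50
iterations, tolerance 1e-6 — configurable, since the appropriate
granularity depends on dataset size.

### The piecewise-cubic transform (method `shambhala2`)

Both datasets are per-gene z-scored; genes of the combined standardized
data are k-means-clustered into B blocks (default 8). Within each block,
the empirical quantiles of the pooled P′ values are mapped onto the
corresponding quantiles of the pooled Q values by a least-squares cubic
polynomial, which is then applied to the block's P′ values. A cubic can
represent mild saturation/expansion warps exactly while remaining cheap
and smooth; where the fitted cubic is non-monotone over the observed range
(possible with ill-matched tails) the fitted values are clamped to their
monotone envelope (`clamp = TRUE`), and blocks pooling fewer than 8 values
fall back to a linear fit. The quantile grid uses up to 500 probe points
(type-7 quantiles), enough to pin down a 4-parameter polynomial.

Both transforms return their result **restored to Q's per-gene scale**
(μ_gQ + z·σ_gQ): the output of step 2 is already "a profile as measured on
Q's platform". This makes the transform examples self-consistent (a P′
equal to Q passes through unchanged; an affine per-gene bias in P′ is
absorbed) and gives the rescaling modes a clean interpretation.

### Rescaling modes

The published rescaling formulas act on the standardized double-transformed
value LE″; `shambhalize()` recovers LE″ = (H_raw − μ_gQ)/σ_gQ and applies:

* **PBR**: LE = μ_gQ + LE″·σ_gQ. On Q-scale output this is the identity —
  PBR *is* the restore-to-Q step — and it uses only Q's summaries, so
  harmonizing a sample alone or inside any batch gives bit-identical
  results. This per-sample independence is the property that makes the
  output bank-appendable, and it is tested exactly.
* **QBR**: LE = μ_gQ + (LE″ − μ_gH)·σ_gQ/σ_gH. The harmonized batch gets
  exactly Q's per-gene mean and sd (tested to 1e-9); the price is batch
  dependence through μ_gH, σ_gH (tested for the dependence direction).
* **RBR**: as QBR with the raw dataset's μ_gR, σ_gR as the target.

QBR and RBR are invariant to any per-gene affine reparameterization of
LE″, so the Q-scale convention affects neither. Genes whose batch sd falls
below `sigma_floor` (1e-8) map to the target mean instead of dividing by
~0.

Per-sample seeding: every stochastic step derives its seed from the master
seed and a hash of the sample identifier, not the sample's position, so a
profile's harmonized value cannot depend on which other profiles happen to
be in the batch.

## Quality metrics

**WM (Watermelon Multisection).** For a dendrogram over n labeled samples,
splits are applied from the root down in order of decreasing merge height
(ties by internal node index, for determinism). After j splits the leaves
form j+1 clusters and the information gain about the labels, normalized by
the total label entropy, is recorded — the observed trajectory. The
maximal trajectory is the fastest possible separation (1 for all j ≥
m − 1 with m classes; greedy class isolation below). The null trajectory
averages the observed trajectory over label permutations on the same tree
(100 by default). With A the mean of a trajectory over splits 1..n−1,

$$\mathrm{wm} = \frac{A_{obs} - A_{null}}{A_{max} - A_{null}},$$

clipped to [0, 1]. Two calibration anchors are enforced by tests: a tree
whose root split separates two classes exactly scores 1, and random labels
score ≈ 0 before clipping. Whether the original metric uses trajectory
areas or terminal gains is not decidable from its qualitative description;
the area form is implemented and documented as this package's choice.
`quality_ratio()` applies the subsampling protocol — 5 samples per tissue
× platform cell, 25 repeats, median of wm_s/wm_p — with both wm values
floored at 1e-6 so degenerate subsamples cannot produce an undefined
ratio. Clustering uses 1 − Pearson distance with average linkage by
default (scale-robust for expression); both are exposed as arguments.

**Concordance.** k1 (OLS slope with intercept) and k2 (through-origin
slope) are combined as k = sign(k1)·√(k1k2) when k1·k2 > 0, else k = 0.
When both slopes are negative the geometric mean keeps their sign (−√·),
keeping k continuous and sign-faithful; the published rule is silent on
that case. Spearman ρ accompanies k and is computed over all shared genes.

**Sign-change curves.** Component i flips when v1 < −w/2 and v2 > +w/2 or
vice versa — strict inequalities, so zeros never flip and w = 0 counts
exact sign opposition only. The width unit is the median absolute value of
the *pooled* vectors (the natural symmetric choice when the two routes are
interchangeable). `divided_by_k` divides v2 by k before counting.

**Classifiers.** kNN uses Euclidean distance in gene space with
deterministic tie-breaks (equal distances: smallest training index; 11-nn
vote ties: the nearest neighbor's class). The SVM route projects onto 20
principal components fitted **on the training set only** (per-gene
centering, no scaling) — the leakage-free reading of "20 principal
components" — then applies a linear-kernel SVM (C = 1, one-vs-one) via
e1071. A pooled-PCA variant is deliberately not offered as default.

**Scores.** LFC_g = case − median(controls) (mean available by flag; the
median matches the metric module's median-profile convention). PAL_p =
Σ role·LFC / Σ|role| over surviving members, and BES_d = ½·mean PAL of
linked pathways + ½·mean LFC of targets. The exact published PAL/BES
normalizations live in proprietary scoring systems; these documented
defaults keep the two structural properties that matter for the analyses
here — linearity in LFC (so a global slope k propagates from expression to
BES) and the pathway-plus-targets composition with the positive-is-
beneficial sign convention.

## The synthetic test bench

`generate_multiplatform()` emulates the study design the metrics assume:
several tissues × two platforms, with

* per-gene baselines from a two-component mixture (70% high-expressed
  N(8, 2²), 30% low tail N(3, 1) on log2 scale);
* **sparse tissue signatures**: 8% of genes carry tissue offsets
  N(0, 0.75²), the rest are tissue-invariant — real tissue identity is
  carried by a minority of genes, and a dense all-gene signature would
  make high-dimensional classification unrealistically error-free;
* **donor noise** N(0, 1.1²) per sample and gene: within-tissue biological
  heterogeneity, the main driver of realistic classification errors;
* a **platform response curve**: values pass through the monotone cubic
  u ↦ a·u³ + b·u on the platform's standardized measurement scale
  (microarray default a = 0.6, b = 0.4 — an S-shaped warp standing in for
  saturation/dynamic-range distortion; sequencing default linear). Being a
  monotone warp of each sample's values, this is exactly the class of
  platform effect a per-sample quantile-based harmonizer can and should
  remove. An earlier per-gene z-space formulation of the distortion was
  rejected: a cross-sample, per-gene relationship is invisible to any
  method that sees one sample at a time, so no parameterization of it can
  be both platform-dominant before harmonization and removable after;
* **per-gene platform bias** N(0, λ²) (λ = 0.1), the probe-affinity-like
  component that is deliberately *not* removable one sample at a time and
  bounds achievable post-harmonization concordance;
* measurement noise N(0, 0.3²), and Poisson count rendering
  (log2(count+1)) for sequencing-like platforms;
* planted case-vs-control shifts: member genes of 6 designated pathways
  move by Δ·sign·role (Δ = 2 log2 units) in case samples, making the
  expected PAL sign knowable in advance. Pathway fixtures are disjoint
  gene sets drawn from genes guaranteed to survive the calibration filter.

The auxiliary pair mirrors the intended roles: P is microarray-like with a
compressed range and only the top 70% of genes by baseline mean (the
"strongly expressed calibration set"); Q is count-rendered over all genes.

Default sizes (3000 genes, 4 tissues, 2 × 4 × 14 control samples + 10
cases per platform, 24 auxiliary samples each) keep the full battery —
two quality-ratio protocols at 25 repeats × 100 permutations plus ~130
per-sample harmonizations — at a few minutes on one CPU; they are the
package's chosen study conditions, not tuned per run.

### What passing the bench does and does not show

The generator carries platform warps, gene biases, count noise, sparse
tissue structure and planted signals, but not: correlated gene modules
(co-expression), batch effects within a platform, sample contamination or
tumor purity variation, sex chromosomes, or realistic pathway topology.
Results on the bench therefore demonstrate that the implementation removes
removable platform structure while preserving planted biology — not that
any particular accuracy value will transfer to real cohorts.

## Numerical choices and degenerate inputs

* Standard deviations use the sample (n − 1) denominator throughout; log
  base is 2; counts load as log2(x + 1).
* Duplicate gene rows collapse by per-sample maximum (favors the reliably
  detected probe); missing values are rejected unless mean-imputation is
  requested.
* Quantile-normalization ties receive the mean of the tied reference
  values; a single-sample matrix returns unchanged with a warning.
* k-means uses a single start per restart; the XPN transform's averaging
  over restarts provides the stability that multiple starts otherwise
  would. Blocks that lose one dataset's samples fall back to the other
  dataset's block estimate.
* Zero-variance genes: z-scores are computed with an sd floor (1e-8), and
  rescaling maps such genes to the target mean with a logged warning.
* Dendrogram split order ties break by internal node index; WM is
  undefined (error) for single-class labels and degenerate trees where the
  maximal trajectory does not exceed the null.

## Known limitations

* The per-gene platform bias that survives per-sample harmonization sets a
  ceiling on cross-platform concordance (observed ρ ≈ 0.96 on the bench at
  λ = 0.1); methods that see whole batches can, in principle, remove it.
* The XPN-style transform at default granularity (K = 25, L = 5, 30
  restarts) is markedly slower than the cubic transform and is sized for
  datasets of tens of samples; for large P/Q the restart count dominates
  runtime.
* The PAL/BES formulas are structural defaults behind a small interface,
  not a reimplementation of any proprietary scoring system; absolute score
  values are not comparable to published clinical scores, only their
  signs, orderings and stability behavior are meaningful here.
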