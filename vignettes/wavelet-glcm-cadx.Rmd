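---
title: "Wavelet-domain GLCM texture classification of lung nodules: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet-domain GLCM texture classification of lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungCADx)
```

# The problem and the modelling idea

Lung nodules — round lesions under 3 cm diameter — appear on thoracic CT as
bright, roughly circular shadows. Most CAD designs segment candidate
lesions first and classify the segments. `lungCADx` implements the opposite
philosophy: no segmentation at all. Each slice is standardized to a
circular body region, transformed to a multiscale wavelet representation,
and described *globally* by second-order texture statistics of each
sub-band. A nodule changes the local texture of the lung fields enough that
a two-feature RBF-SVM can separate slices with nodules from slices without.

The pipeline is: ROI extraction → discrete wavelet transform → GLCM texture
features → attribute/sub-band/pair selection → SVM classification →
contingency-table evaluation. This vignette records the scientific and
numerical choices behind each stage, especially where a design decision was
genuinely open.

# Stage 1: circular ROI

Scanners differ in framing: some embed the axial section in a circle,
others in a rectangle with varying fields of view. `detect_body_circle()`
standardizes this by fitting the dominant circle:

* Edge map: gradient magnitude (central differences) thresholded at its
  Otsu level. Otsu is computed on a 256-bin histogram and is tested against
  a brute-force between-class-variance oracle.
* Circular Hough transform: each edge pixel votes for candidate centers at
  every radius in the search range (default 0.6–1.0 of half the minimum
  dimension, 1-px resolution via a coarse pass plus refinement). The score
  of a candidate is its vote count divided by the ideal perimeter support,
  so large circles are not favoured merely for being large.
* Fallback: if no candidate reaches 25% perimeter support (a constant or
  pathological image), the inscribed circle centered on the image is used
  and flagged. A valid slice must never abort the pipeline.

`apply_roi()` sets everything outside the circle to 0 — black, taken
literally on the working intensity scale — and is idempotent. Whether the
original study fit one circle per scan or per slice is not determinable;
per-slice fitting is used here, which is strictly more general.

# Stage 2: wavelet decomposition

`decompose()` implements the separable 2-D orthonormal DWT for Daubechies
`db1` (Haar), `db2` and `db4`, recursively on the LL band up to depth
*k* ∈ {1, 2}.

Numerical choices:

* **Boundary handling: periodic.** Periodized filter banks keep the
  transform exactly orthonormal, so perfect reconstruction and Parseval
  energy conservation hold to machine precision and are asserted in the
  tests (relative error below 1e−6 is the acceptance bar; the
  implementation achieves ~1e−15). Symmetric extension would bias band
  energies near the border and break exact Parseval.
* **Odd dimensions** are padded to even by edge replication before each
  level and cropped on reconstruction; the pre-padding sizes are recorded
  in the `subband_set`.
* **Orientation convention**, pinned in one place and tested: `LH` is the
  vertical detail (low-pass along rows, high-pass along columns), `HL` the
  horizontal, `HH` the diagonal.
* Images smaller than the filter support (8 px for `db4`) are rejected.

# Stage 3: GLCM texture features

Each sub-band is quantized by linear min–max binning into
*N<sub>g</sub>* = 8 equal-width bins (`quantize()`); a constant band maps
to bin 0 and is flagged degenerate. The co-occurrence matrix (`glcm()`)
counts level pairs at displacement (0, d), (−d, d), (−d, 0), (−d, −d) for
0°/45°/90°/135°, distance *d* = 1, accumulated symmetrically (both
directions) and normalized to sum 1. Symmetric accumulation is what makes
the features exactly rotation-paired: a 90° image rotation maps the 0°
GLCM onto the 90° one and 45° onto 135°, which the tests verify to 1e−9.

Conventions, pinned and documented because several published variants
disagree:

* **Index origin.** Gray levels are 1-based, *i, j* ∈ {1..N<sub>g</sub>}
  (classic Haralick). Cluster shade/prominence and contrast are
  origin-invariant, but autocorrelation, sum average and sum variance are
  not, so the origin matters.
* **Autocorrelation vs correlation.** `Autc` = ΣΣ *i j p(i,j)* (plain
  autocorrelation); `Corr` = (Autc − μ<sub>x</sub>μ<sub>y</sub>) /
  (σ<sub>x</sub>σ<sub>y</sub>). Conflating the two is a common
  transcription error; keeping both separates the raw second moment from
  the normalized one.
* **Sign conventions.** Sum entropy and difference entropy are defined as
  entropies (hence ≥ 0): `Sent` = −Σ p<sub>x+y</sub> log p<sub>x+y</sub>;
  difference variance is a variance (hence ≥ 0):
  `Diffv` = Σ (m − μ<sub>x−y</sub>)² p<sub>x−y</sub>(m).
* **Information measures.** `Imc1` = (HXY − HXY1)/max(HX, HY);
  `Imc2` = sqrt(1 − exp(−2(HXY2 − HXY))), the standard forms, which
  guarantee `Imc2` ∈ [0, 1].
* **Logs** are natural throughout; this only scales entropies.
* **0·log 0 ≡ 0** everywhere.
* **Degenerate GLCMs** (a single nonzero cell) define `Corr`, `Imc1`,
  `Imc2` as 0; every feature is finite on every valid GLCM.

The most consequential unstated choice in this kind of pipeline is what to
do with the black ROI exterior. Counting it would make the (0,0) cell
dominate every GLCM and wash out the lung texture. Here pairs touching any
pixel outside the ROI circle are *excluded*: the circle mask is shrunk
dyadically to each sub-band grid (a coefficient is valid only if its whole
2×2 source block is valid) and masked pixels never enter quantization or
pair counts. Passing `roi = NULL` to `extract_descriptor()` restores the
include-everything behaviour for comparison experiments.

Descriptor bookkeeping (asserted in tests): 19 features × 4 sub-bands = 76
per family/angle at *k* = 1; × 4 angles = 304; × 3 families = 912. At
*k* = 2 there are 7 sub-bands, hence 133/532/1596.

# Stage 4: attribute, sub-band and pair selection

CFS merit of a subset S with |S| = k:
merit = k·r̄<sub>cf</sub> / sqrt(k + k(k−1)·r̄<sub>ff</sub>), with
r̄<sub>cf</sub> the mean absolute feature–class Pearson correlation (the
point-biserial correlation, as the class is binary 0/1) and r̄<sub>ff</sub>
the mean absolute pairwise correlation inside S. Zero-variance features get
correlation 0 rather than NA.

Two deterministic searches are run: best-first (add/remove moves, stall
limit 5, lexicographic tie-breaks) and greedy forward. The original study
ran three search algorithms and kept the features they repeatedly agreed
on; the genetic search is omitted here (it adds stochasticity without
adding a distinct mechanism), and consensus is defined as: features chosen
by *both* searches, topped up to the 11-attribute target by
pooled-variance |t| rank. On planted-feature synthetic data both searches
recover all informative and no noise features across 20 seeded replicates,
and best-first attains the exhaustive-enumeration optimum on problems small
enough to enumerate.

`select_pair()` scores all C(11, 2) = 55 feature pairs by stratified 5-fold
cross-validated accuracy of the RBF-SVM at fixed (C = 100, σ = 4) on
z-standardized folds. Cross-validated accuracy is used as the pair
criterion because the study describes both a |t| ranking and an exhaustive
pair search without stating how pairs were scored; |t| rank is kept as the
tie-breaker. Sub-band selection falls out of the same machinery: the
pipeline runs selection per sub-band and keeps, per (family, depth, angle)
configuration, the sub-band whose best pair cross-validates highest —
matching the one-sub-band-per-row structure of a per-configuration results
table.

# Stage 5: SVM

The kernel is K(a, b) = exp(−‖a−b‖²/σ²); σ is a length scale in
standardized feature units. C is the soft-margin box constraint — not a
kernel prefactor; a constant kernel scale would be absorbed into the dual
coefficients anyway, and C's role as the overfitting control is what the
grids express. Model selection is a grid search over
C ∈ {1, 10, 100, 1000, 10000} × σ ∈ {4, 32} by stratified 5-fold CV with a
fixed derived seed, ties resolved toward smaller C then smaller σ
(preferring the smoother model). The quadratic program is solved by libsvm
via `e1071` (termination tolerance 1e−6); the decision function is then
recomputed in-package from the stored support vectors, dual coefficients
and bias, so a serialized model (JSON) is self-contained.

Two numerical details worth recording:

* Features are z-standardized with *population* (1/n) standard deviations:
  unlike the n−1 estimator this makes training exactly invariant to
  duplicating the training set, a property the tests check to 1e−6.
* The σ grid is only meaningful after standardization; raw wavelet-GLCM
  features span several orders of magnitude.

Scan-level aggregation is a logical OR: one positive slice marks the whole
scan cancerous. This maximizes sensitivity at the cost of specificity,
matching screening practice where a missed nodule is the costly error.

# Stage 6: evaluation

`cadx_metrics()` computes sensitivity TP/(TP+FN), specificity TN/(TN+FP)
and preciseness (TP+TN)/total as percentages; empty denominators yield a
flagged `NA`, never NaN. On the reference operating point TP = 20, FP = 6,
TN = 17, FN = 2 these are 90.91% (90.909...), 73.91% and 82.22%.
`roc_auc()` places thresholds at all distinct scores with tied scores
crossing simultaneously; the trapezoidal area equals the Mann–Whitney pair
statistic with ties counted 1/2, which the tests verify by exhaustive pair
counting and against an independent ROC implementation.

# The phantom: what it emulates and what it does not

`generate_slice()` renders a bright body disk (default radius 0.9 of the
half-width) on black background, two darker axis-aligned elliptical lung
fields at fixed fractional positions, and — for positive slices — one
bright disk-shaped nodule with a 1-px anti-aliased rim, placed uniformly at
random strictly inside a lung field. Defaults: 128 px slices at 0.5 mm
spacing, nodule diameter 8 mm (the clinical range is 2–30 mm; 8 mm is a
mid-range solid nodule and converts to an 8 px radius), additive Gaussian
noise with sd 2% of the body intensity — enough to make co-occurrence
matrices non-degenerate without burying small nodules. Lung geometry is
deliberately *not* randomized so that class differences remain attributable
to the nodule. Every slice derives its own 32-bit seed from the master
seed; generation is bitwise reproducible.

What the phantom does **not** emulate: irregular and part-solid nodule
morphology, vasculature and airway texture inside the lungs, juxtapleural
nodules touching the chest wall, slice-thickness and reconstruction-kernel
effects, and scanner noise correlation. Consequently a passing phantom
study shows that the pipeline's mechanics are correct end to end — ROI
recovery, descriptor computation, selection, training, aggregation — and
that a texture-detectable lesion is found with high sensitivity and
specificity; it does *not* certify clinical performance, where intra-lung
texture variation makes the problem far harder and accuracies well below
100% are expected.

# Problem sizes and determinism

The shipped study sizes mirror the clinical design: 61 training slices (36
positive / 25 negative) and 45 single-slice test scans (23 / 22), with the
full default grid (3 families × 2 depths × 4 angles, best of 4 or 7
sub-bands each). One full run takes on the order of two minutes on a single
core; the acceptance checks repeat it over 5 seeds. Unit tests use 64-px
phantoms (at 1 mm spacing, so the default nodule still fits the smaller
lung fields) and planted-feature synthetic matrices. Every stochastic step
— noise, nodule placement, fold assignment — draws its seed
deterministically from one master seed, and reports are byte-identical
across reruns.

# Known limitations

* Clinical accuracy claims cannot be validated without the clinical
  archives; the phantom saturates near 100% and is a mechanism check, not
  a benchmark.
* The Hough stage assumes a dominant circular body outline; strongly
  elliptical sections are approximated by the best circle.
* The GLCM rotation pairing is exact at the texture level (rotating a
  sub-band); rotating the *input image* additionally permutes the LH/HL
  sub-bands for the asymmetric db2/db4 filters.
* Single-frame little-endian DICOM only; compressed transfer syntaxes and
  sequence elements are rejected.
* The AUC is computed from SVM decision scores; binary predictions alone
  would pin the ROC to a single operating point.
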