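---
title: "Texture analysis of muscle PDFF maps: models, conventions, and the synthetic phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture analysis of muscle PDFF maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdfftexture)
```

## The measurement problem

Chemical shift encoding-based water–fat MRI yields proton density fat
fraction (PDFF) maps: per-voxel percentages of fat proton signal over
total (fat + water) signal. In skeletal muscle, PDFF quantifies fatty
infiltration (myosteatosis). The conventional summary — the mean PDFF over
a segmented region of interest (ROI) — discards the *spatial arrangement*
of fat within the muscle. Texture analysis recovers that information:
first-order (histogram) features describe the distribution of voxel
intensities, second-order features from the gray-level co-occurrence
matrix (GLCM) describe how intensities co-occur at neighboring voxel
pairs.

`pdfftexture` implements this pipeline for bilateral muscle-compartment
ROIs (cervical musculature CE, erector spinae ES, psoas PS; 10 axial
slices per ROI at 1.5 mm isotropic voxels), plus the cohort statistics
layer (sex comparisons, muscle-compartment comparisons, covariate-adjusted
partial correlations) and a synthetic phantom cohort that makes the whole
chain testable without any real MRI data.

## Feature definitions

### Mean PDFF and global features

Mean PDFF is the arithmetic mean of ROI voxel values. The three global
features are moments of the *binned* intensity histogram: with bin centers
$c_b$ and relative frequencies $f_b$,

$$m = \sum_b f_b c_b,\qquad
  m_r = \sum_b f_b (c_b - m)^r,$$

variance $= m_2$ (percent²), skewness $= m_3 / m_2^{3/2}$, kurtosis
$= m_4 / m_2^{2}$.

Choices made here, each surfaced as an argument:

* **Bin count.** The median of Sturges' rule
  ($\lceil \log_2 n\rceil + 1$), Scott's rule
  ($\lceil \mathrm{range}/(3.49\, s\, n^{-1/3})\rceil$) and the
  Freedman–Diaconis rule
  ($\lceil \mathrm{range}/(2\,\mathrm{IQR}\, n^{-1/3})\rceil$). When the
  Scott/FD bin widths collapse ($s = 0$ or $\mathrm{IQR} = 0$) the rule
  falls back to Sturges' count alone, keeping it total.
* **Histogram range.** `[min, max]` of the ROI values, the native
  behavior of all three rules. (The fixed 0–100 % anchoring applies to
  GLCM quantization, below, not to the global histogram.)
* **Kurtosis convention.** Non-excess (a normal sample gives ≈ 3). The
  reference values this package's defaults emulate cluster near 2–3.3,
  consistent with non-excess; psoas values near 1.1–1.6 would be unusual
  under either convention, so this remains a documented judgment call.
* **Binned vs raw moments.** Moments come from the binned histogram
  because the features are defined by intensity-histogram analysis;
  `raw_moments = TRUE` computes raw sample moments for sensitivity
  analysis. The suite verifies the two converge (< 1 % relative error at
  10⁴ bins).
* **Constant ROIs** give variance 0 and `NaN` skewness/kurtosis with the
  reason attached — not an error, since degenerate phantom ROIs (`tau =
  0`) are legitimate inputs.

### GLCM features

PDFF values are quantized to $N_g = 200$ equal-width gray levels anchored
at the physical range: level $=\min(N_g, \lfloor v/100 \cdot N_g\rfloor +
1)$, so 0 % → level 1 and 100 % → level $N_g$. Out-of-range voxels are
clamped at *load* time (with a logged count), making quantization total.

The GLCM is built over the 13 unique offsets of the 26-connected 3D
neighborhood ($d \in \{-1,0,1\}^3\setminus\{0\}$ up to sign),
symmetrically (each pair counted in both orientations), into **one pooled
matrix**. Two conventions deserve explanation:

* **Discretization-length correction.** Diagonal neighbors are physically
  farther apart than axis neighbors, so each pair's contribution is
  weighted by inverse physical distance,
  $w(d) = \min(\text{voxel size}) / \lVert d \cdot \text{voxel
  size}\rVert$: 1 for the shortest axis step, $1/\sqrt2$ and $1/\sqrt3$
  for face and body diagonals at isotropic spacing. `dist_correction =
  FALSE` disables it.
* **Pooled vs averaged directions.** "Averaging the 13 directions" can
  mean one matrix accumulated over all offsets (pooled — the default,
  matching common 3D radiomics toolbox behavior) or 13 per-direction
  matrices normalized then averaged (`aggregate = "average"`). Both are
  implemented; on interior-dominated ROIs they nearly coincide, and the
  pooled set is closed under the octahedral symmetries, which is what
  makes the features rotation invariant (verified exactly in the suite
  over all 48 axis permutations/flips at isotropic spacing).

With $P$ the normalized matrix, marginal $p_i$, $\mu$, $\sigma^2$ its mean
and variance, the eight features are: energy $\sum P^2$; contrast
$\sum (i-j)^2 P$; entropy $-\sum P \log_2 P$ (bits; base 2 keeps values
below the $2\log_2 N_g \approx 15.3$ ceiling, matching the reference
magnitudes 10.8–12.1); homogeneity $\sum P/(1+|i-j|)$; correlation
$(\sum ij P - \mu^2)/\sigma^2$ (NaN for constant ROIs); variance
$\sum (i-\mu)^2 P / N_g^2$ and sum-average $\sum_k k\, p_{x+y}(k) /
N_g^2$ — both carry the $N_g^{-2}$ normalization, without which the
reference magnitudes (0.01–0.13 and ~0.002) are unattainable;
dissimilarity $\sum |i-j| P$.

### Bilateral aggregation

Features (including mean PDFF) are aggregated across sides by muscle
volume: $f = (V_L f_L + V_R f_R)/(V_L + V_R)$, with geometric volume
$V$ = voxel count × voxel volume. A zero-volume or undefined (NaN) side
falls back to the other side; undefinedness propagates only when both
sides are undefined.

## Statistics layer

All feature distributions are treated as non-Gaussian; tests are
unconditional rank tests (no normality gate):

* **Sex comparisons**: two-sided Wilcoxon–Mann–Whitney per feature and
  muscle (plus age and BMI). Exact full-enumeration p-values when the
  combined tie-free sample is ≤ 12; otherwise the tie-corrected,
  continuity-corrected normal approximation. The exhaustive worst-case
  disagreement between the two branches at combined sizes 10–12 is
  0.021 (asserted in the suite); the cutoff of 12 is a pure feasibility
  bound for enumeration.
* **Muscle comparisons**: pairwise Wilcoxon signed-rank (CE–ES, CE–PS,
  ES–PS) on within-subject differences, zeros dropped, same
  exact/asymptotic policy. How a single per-feature p-value across three
  compartments should be formed is under-determined; the package reports
  all three pairwise tests plus a conservative `all(max-p)` summary row
  (the maximum of the three), which flags a feature only when every
  pairwise contrast is significant.
* **Partial correlations**: both variables are residualized on
  `[1, age, bmi]` by least squares and the residuals correlated (Pearson
  by default, per the reference analysis; `method = "spearman"`
  rank-transforms first for monotone robustness). $t = r\sqrt{df/(1-r^2)}$
  with $df = n - 4$. Zero-variance covariates carry no information and
  are dropped (the result then equals the unadjusted correlation);
  mutually collinear covariates are an error. Run per whole cohort and
  per sex.
* No multiple-testing correction by default (matching the primary
  analysis this mirrors); `fdr = TRUE` adds Benjamini–Hochberg columns.

## The synthetic phantom cohort

The generator states the world the analysis assumes, with defaults fixed
once:

* **Geometry**: six mirror-symmetric elliptical-cylinder ROIs (semi-axes
  5 × 3.5 voxels) on a 64×64×10 grid (32×32×10 in the fast test
  configuration) at 1.5 mm isotropic spacing, 10 axial slices each.
* **Texture model**: inside each muscle's ROIs the field is
  `mean_pdff_target + tau * G`, where `G` is white noise Gaussian-smoothed
  to `correlation_length` (default 2 voxels) and re-standardized to exact
  mean 0 / sd 1 over each side's voxels, then clipped to [0, 100]. This
  gives direct control of the global variance (≈ `tau²`) and of GLCM
  contrast/homogeneity (via the correlation length; the suite verifies
  the monotone response). Re-standardization makes `tau = 0` exactly
  constant and the moment contract sharp.
* **Cohort effects** (defaults; all coefficients in
  `default_effect_model()`): 25 men / 54 women; age ~ Uniform(20, 70);
  BMI ~ Normal(24, 5) truncated at 16. Mean PDFF per muscle is a linear
  model — sex-specific intercepts (CE 7.9/9.5, ES 7.4/16.9, PS 3.3/4.4
  %, male/female, i.e. a ~9.5-point female-elevated ES gap), slopes
  0.05 %/year and 0.3 % per kg/m² (fat infiltration rising with age and
  BMI), per-muscle independent residuals (sd 6.5/7.0/4.0). Heterogeneity
  `tau` has male-elevated intercepts (CE 6.0/4.8, ES 7.0/5.2, PS 5.5/4.2)
  plus a small coupling (0.07 per percentage point) to the subject's mean
  residual, so within a muscle heterogeneity rises with unexplained fat —
  which is what makes within-muscle variance–mean partial correlations
  strongly positive while inter-muscle correlations stay null.
* **Why tau is milder than the reference variance levels imply.** Square
  roots of the reference global-variance magnitudes would put `tau` at
  8–12 %; under the Gaussian-plus-clipping model those values clip 25–36 %
  of voxels in the lean compartments and *invert* the programmed
  male-elevated ES variance ordering, because the lean male ES (mean
  ~7 %) clips far more than the fattier female ES (~17 %). Real PDFF
  histograms at those levels are right-skewed rather than clipped
  Gaussian. The generator's contract is the qualitative sign pattern, so
  the defaults keep clipping mild; a muscle whose ROI clips more than
  50 % of voxels is flagged in the volume metadata.
* **Determinism**: every volume is a pure function of (spec, seed);
  per-subject seeds derive deterministically from the master seed. The
  suite asserts bit-identical regeneration.

What a green end-to-end test establishes — and what it does not: the
pipeline recovers programmed sex effects, sign patterns and null
structure from phantoms with the right *statistical* anatomy. The phantom
has no anatomical muscle shapes, no MRI physics (coil profiles, T2*, fat
spectrum, water–fat swaps), no segmentation error, and stationary
Gaussian texture; green tests say nothing about robustness to those
real-data features.

A note on the null calibration check: the inter-muscle partial-correlation
null (~5 % significant at α = 0.05) is evaluated on the sex-stratified
analyses. The pooled-cohort analysis adjusts only age and BMI, and since
sex shifts features of *all* muscles, it remains a common cause inducing
real inter-muscle correlation in the pooled scope — the exact null holds
within sex, which the reference analysis also reports. The calibration
uses 1000 Monte-Carlo replicates rather than a minimal 200 because at 200
the Monte-Carlo standard error (~0.015) is comparable to the ±0.02
acceptance band.

## Numerical and degenerate-input policy

* Volumes and masks must share a grid; no resampling is performed.
* Mask images binarize at > 0.5 (tolerant of interpolated masks).
* ROI voxel extraction uses a fixed scan order (x fastest, then y, then
  z), so every downstream number is bit-reproducible.
* Empty ROIs, no-pair (degenerate) ROIs, all-zero paired differences and
  constant ROIs each have a defined behavior (error, error, flagged
  p = 1, and NaN-with-reason respectively).
* NIfTI-1 I/O is implemented minimally in-package (3D scalar images,
  common dtypes, gzip, both endiannesses, `scl_slope`/`scl_inter`): the
  deployment environment provides no R NIfTI reader, and the pipeline
  deliberately does not depend on orientation metadata, which is passed
  through opaquely.

## Known limitations

* Texture is stationary within each ROI; no spatial gradients or
  anatomy-shaped fields.
* The GLCM variance and sum-average normalization ($N_g^{-2}$) and the
  pooled-direction aggregation follow one reasonable reading of the
  toolbox conventions they emulate; both are configurable, and feature
  *magnitudes* for those two should be compared across software with
  care.
* Exact rank tests enumerate only to combined n = 12; beyond that the
  corrected normal approximation is used (worst-case two-sided deviation
  ~0.02 at the boundary sizes).
* The partial-correlation p-value is parametric on residuals; for heavy
  tails use `method = "spearman"`.
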