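---
title: "Methods: the R1-R2* relaxivity framework in relaxiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the R1-R2* relaxivity framework in relaxiq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxiq)
```

# The model

Paramagnetic iron accelerates both the longitudinal relaxation rate R1 and
the effective transverse rate R2*. Within a single molecular iron
environment — one iron compound in one milieu — both rates are linear in
the iron-compound concentration `[IC]` (mg per wet ml):

$$R_1 = r_1\,[IC] + c_1, \qquad R_2^* = r_2^*\,[IC] + c_2.$$

The slopes are the environment's *iron relaxivities*; they differ between
compounds because R1 and R2* are governed by different molecular and
mesoscopic mechanisms. Eliminating `[IC]` gives

$$R_1 = \frac{r_1}{r_2^*}\,R_2^* + c, \qquad
  c = c_1 - \frac{r_1}{r_2^*}c_2,$$

so within one environment R1 depends linearly on R2* with slope equal to
the ratio of the iron relaxivities. That slope — the *R1-R2\* relaxivity* —
is estimable from MRI alone, and `predict_r1r2star_slope()` /
`predict_r1r2star_intercept()` give the theoretical values for any
parameterised environment. The model's key assumptions are (i) rate
linearity in concentration over the range studied, and (ii) that a region
being fitted is dominated by a single (or at least stable) iron milieu, so
one slope is meaningful.

For heterogeneous milieus the package uses **linear additivity of rate
contributions** (`mixture_rates()`): each compound (and a myelin/lipid
pseudo-compound, if present) adds `r · c` to each rate on a common
baseline. This is a first-order working model chosen by the package — it
ignores compartmental exchange, aggregation-state effects and any
interaction between compounds, and should be read as defining the
simulator's ground truth rather than a validated biophysical claim.

# Estimators

## Sample-level fits

`iron_relaxivity_fit()` regresses per-sample median rates on known
concentrations (in vitro use); `r1r2star_fit()` regresses median R1 on
median R2* across samples. Both are ordinary least squares via `stats::lm`,
reported with a two-sided 95% t-interval on the slope. With exactly two
points the fit is an interpolation: the interval is `(-Inf, Inf)` and the
object is flagged `degenerate` rather than silently precise.

## The binned ROI estimator

`roi_relaxivity()` implements the in vivo procedure:

1. Pool the ROI's voxel R2* values into **36 equal-width bins spanning
   0–50 s⁻¹** (bin width 50/36 ≈ 1.389 s⁻¹). Binning prevents the fit from
   being dominated by whichever R2* regime holds the most voxels.
2. Bins are half-open `[low, high)`; voxels with R2* < 0 or ≥ 50 s⁻¹ are
   **excluded, not clipped** — clipping would manufacture spurious extreme
   bins from outliers.
3. Drop bins whose voxel count is **smaller than 4% of the total ROI voxel
   count** (strict inequality: a bin at exactly 4% is kept). By default the
   4% refers to the ROI count *before* range exclusion
   (`count_base = "roi"`); since the convention is ambiguous in general
   use, `count_base = "in_range"` is available and recorded in the output.
4. Compute the median R2* and median R1 of each retained bin (standard
   even-count midpoint-average medians) and fit a **simple, unweighted**
   regression across the bin medians. Weighting by bin count is available
   (`weight_by_count = TRUE`) but off by default, to match the simple
   regression definition of the estimator.

At least two retained bins are required; otherwise the estimator refuses
with an error naming the problem rather than returning an unstable slope.
One practical consequence of the 4% rule worth knowing: in a ROI whose R2*
values spread uniformly over ~29 occupied bins, the *average* bin holds
only ~3.4% of voxels, so many bins are dropped and the fit rests on the
denser bins. Real R2* distributions are peaked, which is the regime the
filter was designed for.

## The voxel-wise sliding-window map

`sliding_window_map()` fits the same linear model over each voxel's 5×5×5
neighbourhood (125 voxels; truncated at volume edges, no padding), at the
voxel level without binning, provided **at least 10** of the box's voxels
are inside the brain mask; otherwise the output voxel is NaN. The
implementation uses 3-D integral images, so runtime is linear in volume
size; a brute-force per-voxel loop is kept in the test suite as the oracle.
`ratio_map()` (plain R1/R2*) is provided for comparison: it equals the
local slope only when the intercept vanishes, which it generally does not.

# Map fitting

* **R2*/R2** (`fit_r2star`, `fit_r2`): log-linear least squares on the
  echo decay, the standard fast closed form. Per-flip-angle R2* estimates
  are combined by arithmetic mean. Negative fitted rates are clipped to 0
  and flagged (status 1); non-positive signals fail the voxel (NaN, status
  2) instead of producing a silent zero. The log-linear estimator is
  slightly biased at low SNR relative to nonlinear least squares; the test
  suite verifies 1%-level agreement with an `nls` oracle at SNR 100.
* **R1/M0** (`fit_r1_vfa`): the classic variable-flip-angle linearisation
  (S/sin α against S/tan α) with effective angles B1⁺·α. Fitted E1 outside
  (0, 1) fails the voxel.
* **B1⁺ calibration** (`calibrate_b1`): a single scalar transmit factor is
  chosen so the median corrected VFA R1 matches a gold-standard
  inversion-recovery R1 (`fit_r1_ir`) in a reference region with
  effectively constant R1 (e.g. an agar compartment). This deliberately
  simple calibration preserves the contract — VFA R1 anchored to an IR
  gold standard — without modelling smooth spatial transmit fields;
  single-voxel references work but are flagged low-confidence.
* **MTV** (`compute_mtv`): 1 − PD/PD(water), clipped into [0, 1] with a
  clipping flag.
* **MTsat** (`compute_mtsat`): the closed form
  `M0·(B1⁺α)·R1·TR/S_MT − (B1⁺α)²/2 − R1·TR`, with α in **radians** — the
  expression arises from a small-flip-angle expansion, where the angle must
  be in radians for the quadratic term to be meaningful.

# The simulators

`simulate_phantom_dataset()` emulates vials of an iron compound at varying
concentration: hidden true rates from the linear model, SPGR signals for
every (flip angle, echo) pair and an IR series. Defaults follow a typical
3T phantom relaxometry protocol (flip angles 4/8/16/30°, TR 27 ms, five
echoes 4.45–20.85 ms; IR at 50–2000 ms). Noise is additive Gaussian on
magnitude signals — a deliberate simplification; a Rician option
(`rician = TRUE`) applies the noise on quadrature channels instead.
Demonstration relaxivity values used in examples are plausible but
arbitrary; none is claimed as a measured constant.

`simulate_brain_volume()` emulates an anatomically labelled volume in which
each ROI has its own ground-truth slope/intercept and R2* range: voxel R2*
is uniform within the ROI range and R1 = slope·R2* + intercept + Gaussian
noise. What this deliberately does *not* emulate: partial-volume mixing at
ROI borders, spatially correlated noise, susceptibility artefacts,
B0/B1 field structure, vessel or fibre-orientation effects, and realistic
(peaked, skewed) R2* histograms. Passing recovery tests on these volumes
therefore demonstrates correctness of the *estimators*, not robustness to
every property of real brain maps.

Both simulators take an explicit integer seed and are bit-reproducible
given it.

# Statistics

* `ancova_slopes()`: homogeneity of regression slopes — F-test of the
  group×x interaction over a group-intercept model. "One-sided" here means
  the upper tail of the F distribution, which is the standard (and only
  meaningful) tail for this test.
* `regression_ftest()`: simple OLS with the one-sided overall F p-value,
  used per histology predictor; `fdr_bh()` (Benjamini–Hochberg via
  `stats::p.adjust`) corrects across the predictor family.
* `paired_contrast()`: paired t with Cohen's d = mean(diff)/sd(diff)
  (differences taken as b − a). The sd-of-differences denominator is the
  paired-design convention and can exceed 1 substantially when conditions
  are highly correlated; an average-variance denominator is available by
  flag.
* `ks_contrast()`: two-sample Kolmogorov–Smirnov. Comparing distributions
  of different physical quantities (a relaxivity vs a rate) requires prior
  standardization; `standardize = TRUE` z-scores each sample and the output
  records that choice, because a location/scale-free comparison answers a
  different question than a raw one.

# Iron chemistry

`protein_to_iron()` converts an iron-binding-protein concentration to
elemental iron from molecular constants:
iron = protein/MW × ions-per-protein × MW(Fe). The shipped constants
(`iron_protein_specs()`): ferritin 440×10⁶ mg/mol carrying ~2250 iron
ions; holo-transferrin 76×10⁶ mg/mol carrying 2; apo-transferrin 0;
ferrous sulfate heptahydrate 278.02×10³ mg/mol carrying 1. These give
0.286 → 0.29 mg/ml iron per mg/ml ferritin and 1.4696×10⁻³ mg/ml per
mg/ml holo-transferrin. Note that the transferrin figure is sometimes
quoted rounded as 1.4 µg/ml, which is *not* what the constants yield
(1.47); the package reports the computed value and leaves the rounding to
the caller. The conversion applies to controlled in vitro samples only and
is never applied to brain-tissue maps, whose milieu is heterogeneous.

The histology reference table (`brain_iron_histology()`) stores its iron
column under the unit label printed by its aggregated source ("mg/g
protein"), without rescaling: the footnoted microgram-scale conversion in
part of the source literature makes the absolute unit ambiguous, but every
ratio formed within the table (e.g. transferrin/iron) is unit-consistent
regardless, so no silent "fix" is applied. Source keys identify the assay
cohort rather than guessing full citations.

`transferrin_ferritin_ratio()` classifies at a supplied threshold (default
1, a cohort-median split); ties at the threshold go to "high" by default —
an arbitrary but documented and configurable convention, needed because
median splits of even-sized cohorts put observations exactly on the
boundary.

# Numerical conventions and problem sizes

* OLS everywhere is `stats::lm` (QR); slope CIs are two-sided 95%
  t-intervals.
* Medians use R's standard even-count midpoint convention.
* All voxel coordinates are voxel-space; world coordinates live only in
  the NIfTI affine.
* The test suite sizes its simulations for a laptop-class single CPU:
  phantom Monte-Carlo runs use ~100 repeats of 6-sample designs,
  brain-volume recovery uses 50 seeds of 24×14×14 volumes, the
  slope-homogeneity size check uses 10⁴ two-group simulations of 10 points
  each, and enumeration/permutation oracles run at n ≤ 8 per group. These
  sizes were chosen so each suite section completes in seconds to a couple
  of minutes while leaving Monte-Carlo error well below the tolerances
  asserted.

# Known limitations

* No Bloch simulation, k-space, coil/bias fields, susceptibility or
  orientation effects in the simulators; no EPI distortion or motion
  handling in the fitters.
* The B1⁺ calibration is scalar; spatially varying transmit fields are out
  of scope.
* The mixture/myelin rate model is linear additivity by assumption.
* The ROI estimator's 4% filter interacts with broad, flat R2*
  distributions (see above); the binning range 0–50 s⁻¹ targets brain-like
  rate ranges and should be widened for high-iron phantoms.
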