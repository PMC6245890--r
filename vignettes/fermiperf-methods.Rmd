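---
title: "Quantitative stress-perfusion analysis with fermiperf: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative stress-perfusion analysis with fermiperf: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermiperf)
```

`fermiperf` turns a dynamic first-pass perfusion acquisition — stress and
rest short-axis series plus a diluted pre-bolus — into per-segment
myocardial blood flow (MBF), myocardial perfusion reserve (MPR) and
ischemia calls. This vignette documents the models, the tunable parameters
and their defaults, the numerical contracts, and what the synthetic phantom
does and does not emulate.

## The perfusion model

Indicator-dilution theory relates the tissue enhancement curve to the
arterial input function (AIF) by convolution with the tissue impulse
response, $C_t(t) = \int_0^t C_a(s - t_d)\, h(t-s)\, ds$. Deconvolution is
ill-posed, so $h$ is constrained to the Fermi family

$$h(t) = \frac{F}{1 + e^{k (t - \tau_0)}}, \qquad t \ge 0,$$

a monotone non-increasing "plateau then washout" shape with plateau width
$\tau_0$ (s) and decay rate $k$ (1/s). The flow read-out is the
impulse-response amplitude at time zero, $\mathrm{MBF} = h(0) =
F / (1 + e^{-k\tau_0})$, the standard estimator for this family. A separate
arrival delay $t_d$ shifts the AIF rather than entering $h$, which keeps
$h$ monotone.

### Fitting

`fermi_deconvolve()` minimizes the sum of squared residuals between the
measured tissue curve and the discrete forward convolution on the frame
grid, over the window from AIF arrival to the end of the series (a
first-pass-only window can be set via `fit_window`). Numerical choices:

* **Variable projection.** $F$ enters the model linearly, so for any
  $(k, \tau_0, t_d)$ the optimal $F$ has the closed form
  $\max(0, \langle y, b\rangle / \langle b, b\rangle)$ with $b$ the unit-
  amplitude model curve. The nonlinear search therefore runs over three
  parameters only, which removes the amplitude/shape trade-off that makes
  the four-parameter problem poorly conditioned.
* **Bounds and starts.** $k \in [0, 5]$ 1/s, $\tau_0 \in [0, 30]$ s,
  $t_d \in [0, 10]$ s, optimized with bounded Levenberg–Marquardt
  (`minpack.lm::nls.lm`), multistarted at $k_0 \in \{0.05, 0.2, 0.5\}$.
  The best residual wins; ties go to the smaller $k$. A numerically perfect
  fit stops the multistart early.
* **Degenerate limits.** $k = 0$ makes $h \equiv F/2$ regardless of
  $\tau_0$; the product read-out $h(0)$ stays identified even though the
  individual parameters are not, which is why tests assert on MBF, not on
  $(k, \tau_0)$.
* **Units.** The convolution uses the time axis as given (seconds here),
  so $h(0)$ is in 1/s. Maps and segment tables apply `flow_scale = 60` to
  read in mL/g/min-equivalent units. Absolute calibration is out of scope;
  MPR is a ratio and unaffected.

Pixel-wise fitting (`pixelwise_mbf()`) subtracts each pixel's pre-contrast
baseline (mean of the first 5 frames) and fits independently; single-pixel
failures are recorded, never fatal. Per-segment MBF is the **median** over
converged pixels (mean available via `stat`), robust to isolated fit
outliers; MPR is the ratio of segment medians by default, or the median of
pixel-wise ratios via `mpr_order = "pixel"`.

## Dual-bolus AIF and quality control

The blood-pool signal of a full-dose bolus saturates, so the AIF is
measured on a 1:10 diluted pre-bolus and rescaled: `extract_aif()` takes
the mean blood-pool signal per frame, subtracts the baseline (mean of the
first 5 frames) and multiplies by the dose ratio (default 10, matching a
0.0075 then 0.075 mmol/kg protocol). Bolus arrival is the first frame
exceeding baseline + 3 SD. The quality score is peak enhancement over
baseline SD; the SD of the mask-mean curve is estimated by pooling every
masked pixel over the baseline frames (a 5-frame sample SD alone is too
heavy-tailed to gate on). `qc_aif()` fails the case when quality < 5, and
`run_pipeline()` then reports `"quantification-failed"` with no flow
output — the realistic dual-bolus failure mode, reproduced in the phantom
by over-diluting and noising the pre-bolus.

## Motion correction

In-plane respiratory motion is corrected per slice by maximizing the joint
(Pearson) correlation between consecutive dynamics inside an automatically
detected ROI — the padded bounding box of the largest connected component
of high temporal-SD pixels (95th percentile), which isolates the heart
because first-pass enhancement dominates the temporal variance. Contracts
worth knowing:

* Each frame is matched against the **corrected previous dynamic**, so the
  optimized 6 affine parameters are directly the cumulative
  frame-to-reference transform; per-frame errors do not accumulate through
  composition.
* The search is hierarchical — translation first, then the full affine —
  with acceptance thresholds on the correlation improvement
  (`improve_tol = 2e-3` for translation, `affine_tol = 0.02` for the
  affine refinement). The stiffer affine bar exists because the enhancing
  blood pool at bolus arrival genuinely rewards a spurious scale component
  (up to ~6e-3 on a motion-free series); without it, an unidentifiable
  rotation/scale of the near-circular heart drifts in frame by frame.
* The similarity is evaluated on lightly Gaussian-smoothed frames
  (σ = 1 px), which removes a ~0.2 px peak bias introduced by bilinear
  resampling; output frames are resampled from the raw data (bilinear,
  edge-value padding).

On noiseless phantoms these choices give exactly-identity transforms for
motion-free series, ~0.2 px mean absolute error for 5 px breathing
translations, and exact idempotence on re-registration.

## Contours and AHA segments

The temporal maximum intensity projection (per-pixel maximum over frames)
serves as the feature image. `delineate()` finds the blood pool by Otsu
thresholding (brightest connected component; its upper-quartile intensity
is the blood reference, robust to a component that merges pool and
myocardium), then walks 360 polar rays: the endocardial edge is the first
drop below 60% of the blood reference, the epicardial edge the subsequent
drop below 40% of the ring's median intensity, with periodic smoothing
(15° window). The 60/40 fractions were chosen for robustness on the
phantom's contrast ordering (blood ≫ myocardium ≫ background) and are
exposed as arguments. Failure (no pool, or edges missing on >25% of rays)
is an error so the operator can supply contours; `override_contours()`
accepts manual polygons per slice with nesting validation, mirroring the
operator-optimization step of semi-automated analysis.

`build_segment_map()` partitions the annulus by angle from the LV center,
counter-clockwise from the reference angle (default 90°, anterior
RV-insertion at 12 o'clock): 6 sectors on basal (1–6) and mid (7–12)
slices, 4 apical (13–16) — a 16-segment adaptation of the AHA scheme that
drops the apical cap, appropriate for 3 short-axis slices. Territories are
fixed: LAD {1,2,7,8,13,14}, RCA {3,4,9,10,15}, LCX {5,6,11,12,16}. In
`run_pipeline()` one contour set, delineated on the stress MIP (or
supplied), is shared with rest so both maps live on the same geometry;
contours can still be drawn per series by calling `delineate_series()`
directly.

All pixel coordinates in the package and its JSON/CSV exports are 1-based
and inclusive, following R convention.

## The phantom: what it emulates, and what it does not

`make_phantom()` generates the acquisition the pipeline expects: 3
short-axis slices, 120 dynamics at 1 s spacing, 1.9 mm pixels on a 128
matrix (a realistic cardiac FOV), an annular myocardium (endo 8 px, epi
14 px) around a blood-pool disc, and a separate pre-bolus series at 1/10
amplitude on the same time axis. The AIF is a gamma-variate (closed-form
peak at onset + αβ aids testing) with optional recirculation; every
myocardial pixel follows the Fermi forward model of its segment, with
defaults of 3.0 mL/g/min stress and 1.0 mL/g/min rest flow (MPR 3, healthy
vasodilator response) and slower rest washout ($k$ 0.3 vs 0.15 1/s).
Noise is additive i.i.d. Gaussian (SD 2 against a blood peak of 100 —
breath-hold first-pass imaging is high-SNR; Rician noise is a flagged
extension). Motion is an optional sinusoidal in-plane translation
(breathing period 5 s), zero by default since the protocol is breath-held;
tests and the acceptance script enable it explicitly. A transient
multiplicative dark-rim artifact (factor 0.6, innermost subendocardial
ring, 5 frames around the bolus peak) can be enabled to emulate the
classic visual confounder.

Not emulated: through-plane motion, k-t undersampling artifacts,
T1-saturation signal nonlinearity, papillary muscles, and anatomical
variation of wall thickness. Passing phantom tests therefore demonstrates
the correctness of the measurement chain — registration, delineation,
deconvolution arithmetic, calling rules — not robustness to every
scanner-specific artifact of clinical data.

`make_reader_calls()` complements the phantom for the statistics layer:
Bernoulli disease truth at a set prevalence with calls drawn at set
sensitivity/specificity, reproducing reader-group call tables whose
accuracy ordering across training levels the tests verify qualitatively.

## Diagnostic-accuracy statistics

`confusion()` / `accuracy_stats()` compute sensitivity, specificity and
agreement as exact rationals, report to 1 decimal (half away from zero,
matching clinical reporting style) with exact Clopper–Pearson intervals.
McNemar's test for paired calls is the exact binomial version
($2 \Pr(X \le \min(b,c))$ at $p = 1/2$, capped at 1) — defensible at
n ≈ 50 where discordant counts are small — with the asymptotic chi-square
variant as an option. Group comparisons use classical one-way ANOVA plus
pairwise t tests with Bonferroni multiplication; proportions use Pearson
chi-square (no continuity correction) or the Fisher exact test, the only
valid choice for zero-margin tables.

`cohort_consistency_report()` re-derives every reported percentage of the
package's 53-patient validation-cohort fixture from integer counts:
prevalence 16/53, the quantitative confusion matrix reconstructed from the
reported 68.8% sensitivity / 94.3% specificity on the 51 analysable cases
(nearest-integer rounding of rate × denominator gives the unique 11/16 and
33/35), agreement 44/51, and the failure-penalized concordance 44/53 and
specificity 33/37 obtained when the 2 quality-control failures (both
CAD-negative) are counted as missed diagnoses. Each row carries a
pass/fail flag against the reported value.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` choose phantom sizes that keep a
laptop run comfortable while preserving the acquisition's structure:
pipeline-level checks use 64-px matrices with a 7/12 px annulus and 60
frames (~1200 pixel fits per series pair), deconvolution recovery uses a
91-frame curve grid with 50 noisy replicates per condition at peak-SNR 20,
and motion recovery uses the full 128-px phantom over 60 frames. Every
stochastic step is seeded; `run_pipeline()` with a fixed seed and inputs
produces byte-identical CSV/JSON outputs. The acceptance script derives
all sub-seeds from its `--seed` argument.

## Known limitations

* MBF is relative (arbitrary signal units); only MPR-based calls are
  calibrated, via the fixed 1.5 threshold.
* The territory/patient rule is "any ischemic segment" (configurable via
  `min_ischemic_segments`); clinical reads sometimes require contiguity,
  which is not modeled.
* Deformable (non-affine) motion and through-plane motion are out of
  scope; the affine stage deliberately requires strong evidence before
  deviating from pure translation.
* The reader-study layer is qualitative: per-operator variability is
  simulated, not reproduced from data.
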