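---
title: "Patient-calibrated perfusion curve matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-calibrated perfusion curve matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qicgfa)
```

## The problem

Indocyanine green fluorescence angiography (ICGFA) lets a surgeon watch a
dye bolus wash through bowel tissue before constructing an anastomosis, but
interpretation of the raw fluorescence video is subjective: brightness
depends on dose, camera distance, ambient light and residual dye from
earlier injections. The premise of this package is *patient calibration*:
every patient provides their own yardstick, a **reference** angiogram
acquired at the start of the operation before any dissection, against which
the later **determinative** angiogram (the one the transection decision is
made on) is compared. What is compared is the *timing* of the perfusion
curve, not its brightness.

## The matching model

Each region of interest (ROI) yields a time–intensity curve. After
preprocessing (below), a determinative curve $d(t)$ is compared to the
patient's reference curve $r(t)$ by adapting the *reference* along the time
axis only:

$$\hat r_{s,\tau}(t) = r\!\left(\frac{t-\tau}{s}\right),$$

with $r$ taken as 0 outside its recorded domain. Amplitude is never fitted.
Agreement is one minus the normalized L1 disagreement,

$$A(s,\tau) = 1 -
  \frac{\int \lvert \hat r_{s,\tau}(t) - d(t)\rvert\,dt}
       {\int d(t)\,dt},$$

evaluated on the determinative curve's uniform grid and clipped to
$[0,1]$. The fitted $(\hat s, \hat\tau)$ maximize $A$; the maximum is the
*fit peak*. A fit is **accepted** only when the fit peak reaches the 85%
threshold; rejected curves never contribute to a recommendation. A scale
$\hat s < 1$ means the reference had to be *narrowed*: the determinative
perfusion is **brisker** than baseline. $\hat s > 1$ means *slower*. The
companion quantity **briskness** is $1/\hat s$.

The exact published objective is not recoverable (it exists only as a
figure), so the L1-area form above is this package's own definition; it is
consistent with the published companion outputs ("difference in curve
area" alongside the fit peak). A normalized-cross-correlation objective is
selectable via `match_config(objective = "ncc")` for sensitivity checks.

### Optimization and numerical choices

* Grid search over $s$ (121 log-spaced values in $[0.25, 4]$) and $\tau$
  ($[-60, 60]$ s in 0.5 s steps snapped to the sample grid, so a shift is
  an exact index offset). For speed the search stage runs on curves
  decimated to roughly 600 samples; the subsequent refinement always uses
  full resolution.
* Golden-section refinement alternates between $s$ and $\tau$ with
  shrinking brackets around the best cell, to a relative tolerance of
  $10^{-3}$ in $s$. On noiseless synthetic dilations the recovered scale is
  within about $2\times 10^{-4}$ of truth (verified in the test suite
  against an exhaustive dense-grid oracle).
* Grid ties are broken by the smallest $|\tau|$, then the scale closest
  to 1, making the fit deterministic.
* **Known bias.** Because $r$ is defined as 0 outside its domain, a
  time-*compressed* fit ($s<1$) leaves the tail of the recording
  uncovered. If the curves end on a high residual plateau (incomplete dye
  washout), the uncovered tail is penalized and the estimate of $s<1$ is
  biased towards 1. This is a property of the objective, not a bug; it
  does not affect transection recommendations, which act on slowed
  ($s \ge 1$) perfusion. The scale-recovery tests therefore use fully
  decaying bolus curves, where the dense-grid oracle confirms the argmax
  sits at the true dilation.

## Preprocessing

Fixed order, recorded in the output's provenance attribute:
background subtraction → resampling → Savitzky–Golay smoothing → min–max
normalization. The whole pipeline is invariant to positive affine
transforms of the raw intensities.

| parameter | default | meaning |
|---|---|---|
| `baseline_window_s` | 5 s | start-of-recording window whose median is the background estimate (subtracted, floored at 0) |
| `resample_hz` | 10 Hz | common uniform grid for matching; 30 fps input is linearly interpolated |
| `sg_window_s` | 1.0 s | Savitzky–Golay window; the sample count is rounded to the nearest odd integer (31 samples at 30 Hz, 11 at 10 Hz), since an even window is not defined |
| `sg_polyorder` | 3 | filter polynomial order |

Edge samples are smoothed by evaluating the first/last full-window
polynomial fit at their positions, so the filter reproduces polynomials up
to its order exactly everywhere. None of these values are prescribed by
published work; they were fixed once at values typical for 4-minute
30 fps angiograms and are exposed in `preprocess_config()`.

## ROI-level recommendation

Among *accepted* fits, perfusion is **sufficient** at the briskest ROI and
at any ROI at least 95% as brisk ($1/\hat s \ge 0.95 \max_i 1/\hat s_i$).
The recommended transection site is the *most distal* sufficient ROI. If
no fit is accepted the result is an explicit `no_recommendation` — a valid
clinical outcome (the CLI exits 0), mirroring intraoperative cases where
no suitable site exists on a bowel segment. The "95% as fast" rule is
deliberately applied to briskness $1/s$; applying it to another speed
statistic (e.g. time-to-peak) would be a different rule, and the package
documents this choice rather than guessing further.

Agreement with an expert-chosen site is scored with the Jaccard index
between the sufficient zone and the expert zone. Because the published
comparison does not define the expert's *set*, two constructions are
available (`expert_zone()`): the marked ROI alone (`point`) or the marked
ROI plus everything proximal (`proximal_run`, default — a surgeon
transecting at position $k$ implicitly certifies the bowel proximal to
$k$).

## Per-pixel recommendation

`fit_all_pixels()` applies the same fit to every `bin × bin` pixel block
(default 4×4 for noise control; `bin = 1` is literally every pixel) inside
the annotated antimesenteric region. Accepted blocks' briskness values are
pooled; the 75th percentile $q_{75}$ (linear interpolation between order
statistics) becomes the working well-perfused level — chosen so that bowel
that beats the reference curve does not drag the thresholds up. Labels:

* **sufficient** (green): $b \ge 0.75\,q_{75}$;
* **insufficient** (red): $b < 0.25\,q_{75}$, or the fit was rejected;
* **borderline** (orange): in between.

The published wording is ambiguous between fractions *of* the 75th
percentile and percentile *ranks*; the fraction reading is the default and
a percentile-rank mode (`rule_mode = "percentile_rank"`) is provided.
Rejected blocks never influence $q_{75}$. The per-pixel default match grid
is lighter than the ROI grid (61 scale steps, shifts in $[-30, 30]$ s)
because hundreds of block fits run per frame; both grids share the same
objective and refinement. Overlays use a perceptually uniform purple→yellow
scale for continuous metrics and green/orange/red for the recommendation,
alpha-blended (0.45) over the white-light frame, leaving pixels outside
the mask untouched.

## Conventional descriptors

`compute_metrics()` provides the descriptor set used by earlier
quantitative ICGFA work: latency (onset = first sustained crossing of 0.10
for ≥ 1 s; both values configurable, as no published threshold exists),
Fmax, Tmax (peak time minus onset), T½ (first half-peak crossing after
onset, minus onset), least-squares upslope (onset→peak) and downslope
(peak→end), intensity and ±5 s-window gradient at 50 s and 100 s post
peak, TR = T½/Tmax, and the intensity-weighted centre of mass over the
full recording. Slopes use least-squares rather than two-point differences
for noise robustness. T50 and T100 are both peak time plus a constant, so
their rank correlation is exactly 1 on any ROI table — a useful internal
consistency check. Note one analytic subtlety: for a pure linear-inflow
triangle, TR is $(0.5-\theta)/(1-\theta)$ under an onset threshold
$\theta$, i.e. $4/9$ at the default $\theta = 0.1$ and exactly $1/2$ only
as $\theta \to 0$.

## The synthetic phantom

No clinical recordings are distributed, so validation rests on a generator
with known ground truth. Its signal model is a gamma-variate bolus rise
with exponential washout to a residual plateau — the standard dye-transit
family: onset 15 s, peak 45 s, shape 2.5, washout 90 s, plateau 0.35,
emulating inflow and early outflow within a 4-minute, 30 fps angiogram.
The bowel is 11 ROIs at 2 cm spacing (the granularity of a typical
validation judgment series); positions at and beyond the ischemia boundary
(default index 6) are progressively time-dilated (×1.3 per position) *and*
amplitude-attenuated (×0.8). Dilation carries the recoverable signal:
dimness alone is removed by normalization, which is exactly why a
discordant clinically "dim" video must fail through noise/shape, not
brightness. Measurement noise is Gaussian (σ = 0.02 of peak amplitude) on
top of a 0.05 background pedestal. The video variant renders columns with
their nearest ROI position's kinetics in a horizontal band (sharp zone
boundaries), and simulated lactate rises linearly with excess dilation
(base 1.2 mg/dl, slope 2 mg/dl per unit excess, σ = 0.1).

**What a green test does and does not establish.** The phantom has no
peristalsis, camera motion beyond rigid translation, spatial
heterogeneity within a position, recirculation, or photobleaching; its
noise is white. Recovery of the phantom's ischemic boundary shows the
algorithm is implemented correctly and is robust at realistic noise — it
does not reproduce the published clinical agreement numbers, which would
require the original operative videos.

## Statistical reporting

Spearman matrices use average ranks for ties, pairwise-complete
observations (with per-pair n reported), exact p-values for n ≤ 10 without
ties (via the exact null distribution of the rank statistic — equivalent
to full permutation enumeration, computed efficiently) and the
t-approximation otherwise. Verbal interpretation bands are applied to
|rho| with half-open intervals [0, 0.1), [0.1, 0.4), [0.4, 0.7),
[0.7, 0.9), [0.9, 1], closing the gaps the verbal rule leaves between
0.39–0.4 and 0.69–0.7. No multiple-testing correction is applied, matching
the analysis the package mirrors. A published correlation table this
package's layout follows prints "10.00" for the T50↔T100 coefficient; as
rho cannot exceed 1, the package treats the true value as 1.00 (its tests
verify the rank-correlation identity directly).

## Known limitations

* Stabilization is whole-frame translational only; deformable bowel
  tracking is out of scope.
* Background removal is subtractive; no photobleaching or ambient-drift
  correction.
* Cross-bowel-type fitting (small ↔ large) is intentionally unsupported;
  a reference profile carries its segment type.
* The $s<1$ plateau bias described above: briskness comparisons between
  strongly *faster*-than-reference curves with incomplete washout are
  conservative (biased towards "equal").
* TIFF support covers uncompressed grayscale 8/16-bit multi-page files
  (no R TIFF reader is available in the target environment, so the
  package carries a minimal one).
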