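---
title: "Models and methods behind cardiochip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiochip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiochip)
```

`cardiochip` quantifies four kinds of imaging data from vascularized
cardiac microphysiological systems: GCaMP calcium movies, CD31 vessel
z-stacks, tracer time-lapse stacks, and liposome/vessel channel pairs.
Because raw chip imaging data are rarely shared, every analysis here is
paired with a seeded generator that produces the same kind of data with a
known ground truth; the package's correctness claims are parameter-recovery
claims on that synthetic data. This vignette explains the models, the
defaults and why they were chosen, and what the synthetic validation does
and does not establish about real recordings.

## Calcium transients

### Signal model

The generator (`gen_calcium_trace()`) draws a beat train and renders

$$F(t) = F_0 \, e^{-\beta t}\,\bigl(1 + \textstyle\sum_i A_i\, w(t - t_i)\bigr) + \varepsilon(t),$$

where $w$ is a template transient with a linear rise over `time_to_peak`
and an exponential decay with $\tau = \mathrm{decay80}/\ln 5$ — the
simplest shape for which time-to-peak and the 80 %-decay time are
analytically exact, so beat detection can be held to exact expectations.
Inter-beat intervals are gamma distributed with shape $1/\mathrm{CV}^2$
and scale $\mathrm{mean}\cdot\mathrm{CV}^2$ (positive support, exact
mean/CV); amplitudes are lognormal with matched mean and CV. Both reduce
to constants at CV = 0. Photobleaching is a multiplicative exponential;
noise is additive Gaussian. None of these distributional choices comes
from measured chip data — they are stated assumptions, exposed as
parameters.

Defaults represent a healthy recording: 1.04 Hz, IBI CV 0.05, unit
ΔF/F₀ amplitude, `time_to_peak` 0.15 s and `decay80` 0.35 s (typical
GCaMP6f kinetics), 30 s at 10 ms sampling, baseline 100 with noise SD 2
(2 % of a unit-amplitude transient).

### Analysis

`compute_dff()` uses the 10th percentile of the full trace as F₀ by
default: it needs no quiet pre-beat window and tolerates slow drift.
`detect_beats()` finds local maxima with a minimum prominence (default
0.2 × the 5th–95th percentile span) separated by at least 0.2 s (above
the physiological maximum beating rate); per beat, the local baseline is
the minimum since the previous peak, onset is the last upward crossing of
baseline + 10 % of amplitude (linearly interpolated), and the 80 %-decay
time is the first interpolated crossing of peak − 0.8 × amplitude.
`summarize_transients()` computes frequency as 1/mean(IBI) — robust to
partial beats at the trace edges — and CVs over the within-recording
per-beat values with the sample (n−1) standard deviation, matching the
use of one CV point per ROI recording as an arrhythmia index. Fewer than
2 beats gives a missing frequency rather than zero; fewer than 3 gives
missing CVs.

### Known bias of the percentile baseline

When transients overlap (fast beating relative to the decay constant),
the signal never returns to rest and the 10th-percentile F₀ sits a few
percent above the true baseline, deflating ΔF/F₀ amplitudes by the same
few percent. Frequency, both CVs and all *ratios* of amplitudes measured
at a common beating rate are unaffected (the bias cancels); absolute
amplitudes at high beat rates are not. For this reason the longitudinal
fold-change validation simulates day 0 and day 7 at a common frequency,
and the recovered 1.24× amplitude fold carries a residual ≈ −0.03 bias.
Cross-frequency absolute amplitude comparisons on real data should use a
quiet-window F₀ (`f0_method = "prewindow"`).

## Vessel morphometry

### Pipeline

`analyze_vessels()` chains maximum projection, Gaussian blur (σ = 2 px),
triangle thresholding, binary erosion (3 × 3 cross), a binary median
despeckle (radius 2 px), Zhang–Suen thinning with redundancy cleanup, and
skeleton statistics. The triangle threshold is implemented from the
geometric definition — a line from the histogram peak to the farthest
empty tail bin, threshold at the bin of maximum perpendicular distance —
and is tested against an independent brute-force construction over all
bins.

Two parameters the upstream image-processing convention leaves open are
set here by explicit calibration on synthetic ground truth:

- **Erosion depth.** On blurred renders the triangle threshold lands just
  above the background peak and therefore admits the dim halo around each
  vessel (≈ 2.5 px per side). Three erosion iterations cancel this
  dilation almost exactly; with the default `erode_iters = 3` the
  recovered area fraction is unbiased to within ~1 percentage point and
  the recovered mean diameter to within ~5 %. One iteration leaves a
  ≈ +9-point coverage bias.
- **Spur pruning.** Thinning wide tubes creates short terminal spurs at
  corners and junction wedges. `analyze_vessels()` removes terminal
  skeleton branches shorter than 1.2 × the provisional mean diameter
  (area / raw skeleton length) — a self-calibrating threshold that needs
  no user input. Pruning is off by default in the lower-level
  `skeletonize_2d()`.

Skeleton conventions: 8-connectivity throughout; a junction is a skeleton
pixel with ≥ 3 neighbours, with adjacent junction pixels merged so an
X-crossing counts once; an endpoint has exactly one neighbour; path
length counts 1 px per orthogonal step and √2 per diagonal step, a
diagonal being counted only when its two orthogonal intermediates are
absent (otherwise staircase corners would be double-counted). Mean
diameter is total vessel area divided by total network length, and
connectivity is junctions/endpoints — degenerate cases (no endpoints, or
zero length with nonzero area) are flagged, not silently zeroed.

### Two generator regimes

`gen_vessel_network()` has two regimes because no single random geometry
serves both validation purposes:

- **Sparse (`n_segments`)**: sequential random tree growth with tube
  clearance (exceeding two 3-σ tube radii), a ≥ 60° minimum angle between
  branches at a node, and node degree capped at 3. Under these
  constraints the rasterized topology equals the centerline graph, so
  junction/endpoint counts are exactly recoverable (97.5 % exact, all
  within ±1, over 40 seeds in the test suite). The degree cap reflects a
  thinning fact, not biology: an X junction of wide tubes thins into two
  nearby Y junctions.
- **Dense (`target_coverage`)**: wavy near-parallel channels plus sparse
  cross-links, painted until the foreground fraction reaches the target
  (realized coverage lands within one tube of the target and is recorded
  exactly). This geometry is dictated by self-consistency with confluent
  microvascular fields as quantified by area/length morphometry: at ~65 %
  coverage with ~23 µm tubes, vessel area ≈ diameter × total length holds
  only if junction overlap is confined to sparse anastomoses. Random
  stick or lattice geometries put 15–20 % of tube area into junction
  overlap, which makes the area/length diameter unrecoverable *by
  construction* — not a pipeline flaw but a geometry inconsistent with
  the morphometric identity the measurement relies on.

Per-segment diameters are normal with the requested mean/SD (clamped to
≥ 2 px); per-segment intensities are normal (default 140 ± 25 over a
background of 15 with pixel noise SD 8), giving the dominant narrow
background peak plus broad foreground hump typical of confocal MIP
histograms — the regime the triangle threshold is designed for.
Anti-aliasing is off, so pixel counts are exact and the recorded coverage
is exactly the emitted mask's foreground fraction.

### What the renders do not emulate

No optics (PSF, depth attenuation), no 3D lumen structure (rendering is
2D, matching max-projection analysis), no intensity gradients along
vessels, no autofluorescent debris. Passing recovery tests therefore
demonstrates the pipeline's correctness on well-formed images with known
answers; on real images the triangle threshold and the erosion depth
remain the operator-sensitive steps, which is why every mask records its
full provenance (threshold value, tail side, all cleanup parameters).

## Permeability

The forward model is linear tracer influx into the perivascular tissue:

$$I_t(t) = I_b + P\,(I_v - I_b)\,\frac{S}{V}\,t, \qquad \frac{S}{V} = \frac{4}{d}$$

for a cylinder of diameter $d$. The estimator inverts it by least
squares: $P = \mathrm{slope}/(I_v - I_b) \times d/4$ (in cm s⁻¹; the
µm→cm conversion is tested explicitly). The cylindrical V/S = d/4 is a
convention choice — the measurement partition (lumen mean, perivascular
band mean, background) and the geometric factor are selectable, and the
area/perimeter alternative can be supplied through `geometric_factor`.

A caveat that matters for synthetic validation: with the d/4 convention,
permeabilities of a few 10⁻⁶ cm s⁻¹ and a ~23 µm vessel imply tissue
intensities formally exceeding the vessel intensity within a 12-minute
window. Real systems do not behave this way because the perivascular
volume per vessel surface is much larger than d/4; the generator keeps
the stated convention, emits the unclipped linear model, and flags
`linear_regime_violated` in the ground truth. The estimator's
saturation-frame exclusion (frames with $I_t \ge 0.95\,I_v$, a guard
against dye equilibration in real data) must be disabled
(`saturation_frac = Inf`) when analyzing such deliberately unclipped
stacks; recovery is then exact to numerical precision, and within 10 %
under 1 % noise.

## Extravasation

`gen_extravasation_pair()` places a requested number of liposome-positive
pixels so that exactly the requested fraction (to the nearest achievable
pixel) falls outside the vessel mask. `extravascular_fraction()`
thresholds the liposome channel (triangle by default, or an explicit
value) and counts positives outside the mask, optionally dilated
(default 1 px) to absorb registration slack at the vessel wall; with
dilation 0 the generated fraction is recovered exactly.

## Group comparisons

`compare_to_control()` assesses normality per group (Shapiro–Wilk at
α = 0.05; the normality test is a convention choice, as is Holm
adjustment for Dunn's test — the graphing-software defaults this
workflow mirrors do not document theirs). All groups normal → one-way
ANOVA with Dunnett contrasts against the control (via `multcomp`);
otherwise Kruskal–Wallis with Dunn's rank z-tests (tie-corrected,
implemented here and cross-checked against an independent rank-arithmetic
oracle) Holm-adjusted over the control comparisons. Under the null (four
normal groups, n = 12, 2000 replicates) the family-wise rejection rate
sits inside [0.035, 0.065] — the mixture of the exact-FWER Dunnett branch
and the occasionally-triggered nonparametric branch stays near nominal.
Two-way designs (e.g. condition × day) are routine `aov()` applications
and are not wrapped.

## Problem sizes and numerical choices

The validation suite uses 30 s traces at 10 ms (the acquisition setting
the data emulate), 12 traces per condition for recovery means, 1024² px
renders (20 per condition) for morphometry recovery and 512² for unit
tests — sizes chosen so the full suite exercises the pipelines at the
study's native scale while remaining a desk-scale computation. Thinning
runs in compiled code (Rcpp) with a pure-R reference implementation kept
for cross-checking. Ties and degenerate inputs are handled explicitly:
zero beats is a valid empty result; two equal zero-variance groups give
p = 1 with a flag; an empty mask, a zero-length skeleton and a
zero-positive liposome image are flagged results, never silent zeros.

## Limitations

- Recovery results certify the pipelines against their own forward
  models; they do not certify the forward models against real chips.
- The area/length diameter is intrinsically biased low in junction-dense
  fields; the generator avoids that regime because the study's own
  numbers imply it, but real pathological networks may not.
- Absolute ΔF/F₀ amplitudes at high beat rates inherit the percentile-F₀
  bias described above.
- The permeability geometric factor is a convention; values are
  comparable in kind, not guaranteed identical to other conventions on
  real data.
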