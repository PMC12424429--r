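---
title: "Quantifying transient membrane trapping from single-molecule trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transient membrane trapping from single-molecule trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptrap)
```

## The measurement problem

Membrane-anchored signaling proteins such as small GTPases diffuse laterally
in the inner leaflet of the plasma membrane. When such a molecule engages a
binding partner or a nanodomain, its motion changes in two measurable ways:
its short-timescale diffusion coefficient drops, and it shows *transient
trapping* — episodes of a few hundred milliseconds during which the molecule
stays inside a zone of roughly 100 nm diameter. Single-molecule TIRF imaging
at video rate (33-ms frames) resolves both signatures on a per-molecule
basis, and their population statistics (temporal fraction of trapped time,
trapping frequency, event durations, zone sizes, immobile fractions) turn
out to be far more sensitive readouts of activation state than bulk
biochemistry.

`sptrap` implements the full trajectory-level analysis chain behind such
measurements, starting from tidy localization tables (one row per spot; any
tracker can produce them) and ending in per-cell statistics. Because raw
imaging data for this kind of experiment is rarely shareable, the package
also ships a seeded generative model of the same experiments, so that every
estimator can be validated by parameter recovery — simulate with known
ground truth, analyze, and compare.

## Data model

A `track_set` holds trajectories of one experiment: strictly consecutive
frame sequences of (x, y) positions in micrometres at one frame interval
`dt` (default 1/30 s), grouped by cell and imaging channel. Frame gaps are
split on import (`read_tracks()`) because the detectors assume consecutive
frames; how blinking or broken tracks should be re-linked is a tracker
question that this package deliberately does not answer. Quantitative
analysis uses trajectories of at least 10 frames (`filter_min_length()`),
inclusive.

Each channel carries a `channel_model`: the per-axis localization precision
`sigma_axis` (SD of repeated localizations of a stationary emitter; 14.0 nm
for the green probe, 18.7 nm for the red one at video rate) and the
photobleaching lifetime (10.4 s and 8.1 s). The precision enters the
zone-size correction and the simulator; the lifetime truncates simulated
trajectories. The quoted precisions are treated as *per-axis* values; if
they were radial SDs instead, calibrated immobile thresholds would shrink
by another factor of two (see "Known limitations").

## Diffusion: overlapping-window MSD and D200ms

`compute_msd()` uses every overlapping pair of positions n frames apart:
MSD(n·dt) = mean over j of |r(j+n) − r(j)|², j = 1 … N − n. `estimate_d200()`
fits an ordinary least-squares line (with intercept, unweighted) through the
MSD at lags 5, 6, 7 — the 167/200/233-ms points at video rate — and reports
slope/4 as the diffusion coefficient on the ~200 ms timescale. Static
localization noise adds an approximately lag-independent offset 4σ² that
lands in the intercept, leaving the slope estimator unbiased; this is tested
with a paired simulation.

Two numerical choices matter:

* **Window extent.** By default the MSD uses all overlapping windows of the
  full trajectory, which minimizes estimator variance. `first_frames = 10`
  restricts the estimate to the first 330 ms of each track for literal
  protocol replication. The difference is not cosmetic: on minimum-length
  (10-frame) tracks the 3-lag slope has so much skewed noise that the
  *median* estimate underestimates the true D by ~40% even though the mean
  is unbiased, and a quarter of genuinely mobile tracks fall below any
  immobile threshold. Population summaries in this package therefore rely
  on the full-window default, under which median recovery holds to within a
  few percent at realistic (bleach-limited) track lengths.
* **Negative estimates.** Short noisy tracks can produce negative slopes.
  They are retained, not clipped, so that percentile-based threshold
  calibration stays well defined, and they classify as immobile.

`classify_mobility()` calls a trajectory immobile when its D200ms lies
strictly below a threshold (default 0.009 µm²/s).
`calibrate_immobile_threshold()` reproduces how such a threshold is set in
practice: the 95th percentile (type-7, linear interpolation) of the D200ms
values of an immobilized reference population.

## The transient-trapping detector

`detect_events()` scans each trajectory with a greedy two-pass rule:

1. anchor a candidate window at frame i and grow it one frame at a time as
   long as *every* member lies within the detection radius (50 nm, i.e. a
   100-nm-diameter zone) of the running centroid;
2. verify all members against the final centroid, trimming trailing
   violators; accept if the window still spans at least 5 frames (166.7 ms
   at video rate); resume scanning after the accepted event.

Events therefore never overlap, ties break toward the earliest start, and a
single excursion frame terminates an event — there is no excursion
tolerance. This is one defensible instantiation of the published
residency-based detection idea; the fragmentation cost of the
no-tolerance rule can be quantified directly with the simulator (about
1.5% of event frames stray beyond 50 nm of the centroid at 10-nm
confinement and 14-nm noise, so ~13% of ten-frame events split).

Zone sizes are reported per event: `raw_sd` is the radial SD of the event's
positions about their centroid (n − 1 normalization), and the
localization-noise contribution is removed in quadrature,
`corrected_sd = sqrt(raw_sd² − 2σ²)` (floored at zero). For isotropic
Gaussian noise this equals the correction obtained by fitting a 2-D
Gaussian to the event's coordinates, but it is closed-form and directly
testable; the conventional reporting unit is the area `corrected_sd²` in
multiples of π nm². Per-cell statistics (`summarize_cells()`) follow the
standard definitions: temporal fraction = 100 × total event time / total
trajectory time, frequency = events per second of trajectory time, with
durations counted as frames × dt.

## Dual-color colocalization

`pair_distance_density()` accumulates, frame by frame, all inter-channel
pair distances inside an ROI into 50-nm annuli (0–500 nm), dividing each
count by its annulus area. Under spatial independence this density is flat,
so the `coloc_index()` — the 0–50 nm density over the 400–500 nm density —
equals 1 for a CSR null and grows with true association. Because a ratio of
*raw* pair counts between annuli of very different area is not comparable
across geometries, area normalization is the default; `normalize = FALSE`
gives the literal count ratio for replication. No edge correction is
applied; a warning enforces an ROI large relative to the 500-nm outer
radius. `detect_coloc_events()` applies the standard 240-nm frame-wise
criterion, at which truly co-moving molecules with 14.0/18.7-nm channel
noises score as colocalized in ≥ 99% of frames.

## The generative model

`sim_preset()` + `simulate_experiment()` produce seeded, bit-reproducible
multi-cell datasets with the statistical structure the analysis assumes:

* two-state continuous-time switching with exponential dwell means for the
  free and trapped states (occupancy = trap/(trap + free));
* free state: 2-D Brownian steps, per-axis variance 2·D·dt;
* trapped state: i.i.d. Gaussian scatter (per-axis SD `trap_conf_sd`, 10 nm
  default) about a fixed trap center — the simplest model consistent with
  the zone-size statistic; Ornstein–Uhlenbeck dynamics would be the natural
  extension point;
* per-axis localization noise on every position; exponential photobleaching
  truncating trajectories (geometric per-frame survival) capped by a
  300-frame movie;
* hidden state labels retained on every trajectory for oracle tests.

Dwells are rounded to whole frames (switches at frame boundaries), keeping
the mean dwell and hence the hidden-state occupancy unbiased — a property
the test suite checks by the law of large numbers. Two second-order details
deserve mention because naive implementations get them wrong. First, a trap
center must sit one diffusion step away from the last observed free
position (molecules walk into traps between frames); placing it exactly
under the previous localization hands the detector one artificial event
frame per event (~10% inflation of the temporal fraction). Second, a free
dwell shorter than half a frame is invisible at the frame clock but still
displaces the molecule, so consecutive trap runs get distinct centers
displaced by the actual sub-frame free time.

Two closed-form oracles connect ground truth to detector output for
exponential dwells with mean τ and threshold time T = 5·dt:

* `expected_detected_fraction()`: the length-biased fraction of trapped
  time lying in dwells of at least T is e^(−T/τ)(1 + T/τ); multiplied by
  the occupancy it predicts the detected temporal fraction.
* `expected_detected_mean_duration()`: dwells conditioned on exceeding T
  have mean T + τ (memorylessness).

`calibrate_occupancy()` inverts the first oracle, which is how the shipped
presets (`sim_presets()`) are built from printed population summaries: a
pre-stimulation wild-type-like condition (D 0.53 µm²/s, 3.2% temporal
fraction, 239-ms mean duration), a 2-min post-stimulation peak (8.1%,
338 ms), GEF-like (0.1 µm²/s, 46%, 308 ms) and effector-kinase-like
(0.093 µm²/s, 23%, 328 ms) conditions, and a stationary-emitter reference.
These presets are reverse-engineered validation fixtures, not biological
claims.

### What the oracles do and do not predict

The oracles assume isolated exponential dwells. Simulation shows where that
assumption holds and where it breaks:

* At low occupancy and fast free diffusion (the wild-type-like regime) the
  detected temporal fraction tracks the calibrated prediction to within a
  few percent.
* Detected mean durations run ~10% below T + τ: a frame-counting detector
  measures E[duration | ≥ 5 frames] ≈ τ + 4.5·dt rather than τ + 5·dt,
  and fragmentation plus right-censoring at bleach-truncated trajectory
  ends trims a further few percent.
* At high occupancy with slow free diffusion (the GEF-like regime, mean
  free dwell ~2 frames, free step ~82 nm/axis), a large share of trapped
  time lies in sub-threshold dwells, and the detector chains such dwells
  across one-to-two-frame excursions into detectable events. The detected
  fraction then *exceeds* the length-bias prediction substantially (tens of
  percent). Calibrations through the oracle are only trustworthy in the
  dilute-trapping regime.

The same honesty applies to the immobile threshold: the 95th percentile of
simulated stationary emitters at 14-nm precision and 10-frame tracks is
≈ 0.003 µm²/s, a factor ~3 below the canonical 0.009 µm²/s, which was
calibrated on real reference data ("leaking" molecules from dead cells are
not perfectly stationary). And the recovered immobile fraction of a
mixture slightly overshoots the true immobile weight (≈ 3.8% vs 3.2%)
because the shortest bleach-truncated mobile tracks leak below any
threshold; this ~0.5–0.8 percentage-point leakage is intrinsic to the
track-length distribution, not to the classifier.

What the generator does **not** emulate: hop diffusion between
cytoskeleton-fenced compartments (invisible at 33-ms resolution), anomalous
diffusion, Ornstein–Uhlenbeck confinement dynamics, tracker artifacts
(misconnections, blinking-induced gaps beyond simple splitting), spatial
heterogeneity of traps within a cell, and intensity photophysics beyond a
constant mean. Passing recovery tests therefore demonstrates estimator
correctness under the stated model, not robustness to every failure mode of
real movies.

## Statistics layer

`welch_t()`, `mann_whitney()` and `spearman_rho()` wrap the standard
two-sided tests (Welch–Satterthwaite dof; exact Mann-Whitney enumeration for
both n ≤ 8 without ties, tie-corrected normal approximation otherwise —
verified against exhaustive enumeration). `box_summary()` uses type-7
quartiles and 1.5×IQR whiskers, the convention used in the field's figures.
`bonferroni_stars()` applies strict thresholds 0.05/m, 0.01/m, 0.001/m; at
m = 3 these print as the familiar 0.017/0.003/0.0003.
`fit_exponential_lifetime()` is the exponential MLE (sample mean) with an
optional left-truncation correction (mean − T), as used for photobleaching
lifetimes and dwell-time fits.

## Problem sizes and reproducibility

The shipped validation suite simulates experiments of 20 cells × 200
trajectories (the scale of one imaging session) for temporal-fraction
recovery, ~5,000 trajectories for diffusion-median recovery, and 10,000
mixed trajectories for immobile-fraction recovery; these sizes put the
Monte-Carlo error of each recovered quantity well below the assertion
bands while keeping a full run in the minutes range on one core. Every
simulation is reproducible bit-exactly from (preset, seed); multi-cell
experiments use per-cell substream seeds so cells are independent and
results do not depend on the order of generation.

## Known limitations

* The detector has no excursion tolerance; real analyses sometimes allow
  one stray frame. The effect is quantifiable here (fragmentation rate vs
  confinement SD) but not configurable away.
* The per-axis reading of the quoted localization precisions is an
  assumption; a radial reading would halve the noise variance used in the
  zone-size correction and threshold calibration.
* Oracle-based calibration breaks outside the dilute-trapping regime (see
  above); treat high-occupancy recoveries as demonstrations of detector
  behavior, not as inversions.
* Registration between the two color channels is assumed perfect;
  `pair_preset()` exposes a systematic offset parameter to study the
  sensitivity, but the aperture-mask registration procedure itself is out
  of scope, as are spot localization and track linking.
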