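# sptrap

Single-molecule trajectory analysis of transient membrane trapping.

Membrane-anchored signaling proteins (the motivating case is KRAS and its
partners SOS1 and BRAF in the inner leaflet of the plasma membrane) diffuse
freely until they engage a binding partner or nanodomain, at which point
they show two quantifiable signatures in video-rate single-molecule TIRF
recordings: a drop in the short-timescale diffusion coefficient and
*transient trapping* — sub-second episodes confined to a ~100-nm-diameter
zone. The temporal fraction, frequency, duration and zone size of these
events, together with per-trajectory diffusion coefficients, read out
activation state molecule by molecule, with far better sensitivity than
bulk assays such as western blotting.

`sptrap` is the trajectory-level analysis chain for such experiments. It
starts from tidy localization tables (any SPT tracker can produce them) and
provides:

* **Trajectory I/O** — `read_tracks()` / `write_tracks()` (CSV, one spot
  per row), gap-splitting, the ≥ 10-frame analysis filter.
* **Diffusion** — overlapping-window MSD (`compute_msd()`); D<sub>200ms</sub>
  by an OLS line through the MSD at the 167/200/233-ms lags, slope/4
  (`estimate_d200()`, `fit_diffusion()`); immobile classification below a
  threshold (default 0.009 µm²/s) calibrated as the 95th percentile of an
  immobilized reference (`calibrate_immobile_threshold()`).
* **Trapping detection** — residency of ≥ 5 frames within a 50-nm radius of
  the event centroid, via a greedy two-pass scan (`detect_events()`,
  `fit_trapping()`); precision-corrected zone sizes
  `corrected_sd = sqrt(raw_sd² − 2σ²)` reported as areas in multiples of
  π nm²; per-cell temporal fractions and frequencies.
* **Dual-color colocalization** — area-normalized pair-distance densities
  in 50-nm annuli, the 0–50 / 400–500 nm colocalization index (= 1 under
  spatial randomness), and 240-nm frame-wise colocalization events.
* **Recruitment** — background-subtracted intensity-sum time courses
  relative to a reference time point, and spot densities normalized to
  expression level and area.
* **Statistics** — Welch's t, Mann-Whitney U, Spearman's ρ, Bonferroni
  star thresholds, box-whisker summaries (type-7 quartiles, 1.5×IQR
  whiskers), exponential lifetime fits.
* **A generative model** — seeded two-state (free Brownian / trapped)
  trajectory simulation with localization noise and photobleaching
  (`sim_preset()`, `simulate_experiment()`, `simulate_pair()`), plus
  closed-form dwell-truncation oracles so every estimator is validated by
  parameter recovery without any external data.

## Worked example

Simulate a 2-min-post-stimulation-like experiment (20 cells × 200
trajectories; free D 0.53 µm²/s, 338-ms trap dwells, occupancy calibrated
so the expected detected temporal fraction is 8.1%), then run the trapping
and diffusion analyses:

```r
library(sptrap)

preset <- sim_presets("wt_post2")
tracks <- simulate_experiment(preset, seed = 7)

trap <- fit_trapping(tracks, trap_params(), sigma_axis_nm = 14)
trap
#> transient trapping: 5161 events in 20 cell(s)
#> trapping detector: radius 50 nm, >= 5 frames, trajectories >= 10 frames
#>  mean per-cell temporal fraction 8.35%, frequency 0.203 events/s
#>  mean event duration 412 ms, mean zone area 223 pi nm^2

diff <- fit_diffusion(filter_min_length(tracks, 10, quiet = TRUE))
summarize_diffusion(diff)
#> diffusion summary: n = 3880 trajectories
#> median D200ms   0.4785 um^2/s
#> immobile        1.01% (threshold 0.009 um^2/s)

box_summary(trap$cells$temporal_fraction)
#> box summary (n = 20): median 8.225, mean 8.348
#>  box [8.087, 8.641], whiskers [7.653, 9.057], range [7.653, 9.057]

spearman_rho(trap$events$duration_s, trap$events$zone_area_pi_nm2)
#> Spearman rho = -0.114 (n = 5161, p = 1.79e-16)
```

Reading the numbers: the detector recovers a mean per-cell temporal
fraction of 8.35% against the 8.1% the preset was calibrated to. The median
D<sub>200ms</sub> of 0.48 µm²/s sits below the 0.53 µm²/s free-state
diffusivity because trapped episodes drag the apparent short-timescale
coefficient down — the same signature seen when comparing stimulated to
resting cells. The mean event duration (412 ms) and the slightly negative
duration–size rank correlation mirror the behavior of the real
measurements this pipeline emulates.

A thin command-line front end wraps the same functions:

```sh
inst/bin/sptrap simulate --preset wt_post2 --seed 42 --out tracks.csv
inst/bin/sptrap analyze trap --in tracks.csv --sigma-nm 14 --out results/
inst/bin/sptrap report --events results/events.csv --out results/
```

Every output is written atomically with a `.meta.json` sidecar recording
parameters, seed and package version, so `(config, seed)` fully determine
all outputs.

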