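# aggflux

Exchange kinetics and quantitative time-lapse imaging of neuronal protein
aggregates.

Neurons expressing an aggregation-prone reporter protein — the motivating
system is a polyglutamine-expanded huntingtin exon-1 fragment — sequester
it into micron-scale inclusions, most of them axonal. Long-term confocal
imaging shows near-linearly rising aggregate counts and declining
cytosolic fluorescence; in-situ pulse-chase labeling and FRAP show that
each aggregate continually exchanges protein with the cytosol (recovery
time constant ≈ 9 h), i.e. aggregates act as concentrated sinks near
equilibrium with the soluble pool. A ubiquitination-deficient variant
(K6,9R) instead forms few, often nuclear, non-exchanging deposits.

`aggflux` is for researchers who want to analyze such experiments — or
stress-test analysis choices against known ground truth. It provides:

* **kinetics** — an explicit exchange model with pulse-chase label
  bookkeeping. Per label state *x* and aggregate *i*:

  d*c_x*/dt = s·1[x = synth] − k_deg·*c_x* − (n·k_on·*c_x* − k_off·Σᵢ *a_i,x*)/V,
  d*a_i,x*/dt = k_on·*c_x* − k_off·*a_i,x*,

  with threshold Poisson nucleation at rate V·k_nuc·max(0, c − c_nuc) and
  compartment placement probabilities. Calibrated `"WT"` (k_off = 1/9 h⁻¹,
  axon-dominated placement) and `"KR"` (k_off = 0, nucleus-biased,
  ~25× slower nucleation) presets are included.
* **synthgen** — neuron geometries (somata, nuclei, dendrites, faint
  axons) and a renderer producing multi-channel, 12-plane z-stack, 12-bit
  time-lapse series with Poisson + read noise and paired ground-truth
  tables; standard protocols (`longterm_*`, `pulsechase_*`, `frap`,
  `localization_*`) wire model, labeling schedule and acquisition timing
  together.
* **detect/track** — punctum detection on maximal-intensity projections
  (band-pass, robust thresholds, blobness, sub-pixel refinement) and
  deterministic greedy linking with gap closing and merge bookkeeping.
* **quantify/compartment/turnover** — ROI and cytosolic intensity traces,
  t = 0 normalization, per-FOV count curves, axon/dendrite/soma/nucleus
  assignment from the morphology channel across all frames of a track,
  single-exponential FRAP fits and pulse-chase old/new-label summaries.
* **pipeline** — `run_pipeline()` for reproducible end-to-end runs with
  CSV/JSON artifacts and OME-TIFF I/O, plus a thin CLI (`inst/cli/aggflux`).

See the methods vignette (`vignettes/exchange-kinetics.Rmd`) for the model,
its assumptions, parameter calibration, and known limitations.

## Worked example

Simulate a quarter-scale field with 32 aggregates placed by the wild-type
localization preset, then detect, track and classify them:

```r
library(aggflux)
b <- run_pipeline(list(
  protocol = "localization_WT", seed = 42,
  sim = list(fov_shape = c(240L, 320L), duration_h = 8)))
str(b$summary)
#> List of 8
#>  $ protocol           : chr "localization_WT"
#>  $ seed               : num 42
#>  $ n_frames           : int 5
#>  $ n_tracks           : int 31
#>  $ n_detections       : int 154
#>  $ axon_fraction      : num 0.839
#>  $ nuclear_fraction   : num 0
#>  $ unresolved_fraction: num 0
```

31 tracks were recovered from the 32 rendered aggregates (two nearby
puncta merge optically) and 84% of them are called axonal, reflecting the
preset's 83% axonal placement. `b$tracks`, `b$calls` and `b$traces` hold the
per-track tables; setting `out_dir` writes them as CSV together with a
`summary.json` and the run log.

The kinetic model is usable on its own, e.g. the closed-form FRAP
recovery of the WT preset:

```r
wt <- kinetic_preset("WT")
fc <- frap_recovery_curve(wt, c_ambient = 100, horizon = 5, dt = 5/60)
fit_frap(fc, bleach_time = 0, fit_config = list(pre_bleach_value = 1))
#> <frap_fit> tau=9 h, mobile fraction=1.000, f0=6.86e-08, f_inf=1 (rms 3.07e-08)
```

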