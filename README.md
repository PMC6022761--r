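# mtdi — microtubule dynamic instability analysis

`mtdi` is an R package and analysis workflow for quantifying microtubule
dynamic instability from in vitro TIRF experiments and live-cell imaging.
It covers the full computational chain those experiments need:

* **Imaging** — two-channel movies (stabilized seeds + dynamic tubulin) to
  kymographs to length-vs-time traces: seed detection, drift correction by
  Fourier cross-correlation, axis resampling with a ±4-pixel crop and
  max-projection, and intensity-threshold length tracking.
* **In vitro kinetics** — sliding-window phase segmentation into
  polymerization/depolymerization events; per-event rates from first and
  last points; the rate-versus-concentration regression whose slope gives
  the apparent on-rate constant
  *k*<sub>on</sub> = slope × 1750 / 60 subunits·µM⁻¹·s⁻¹
  (1750 dimers per µm of a 14-protofilament lattice, 8-nm repeat) and whose
  x-intercept is the apparent critical concentration; cumulative
  distributions of length at catastrophe.
* **Tubulin washout** — washout window from the background channel (k·σ
  drop rule), pre-washout polymerization rate, catastrophe calling by
  iterative 5-point regressions against a −150 nm·s⁻¹ slope threshold, and
  the slow (pre-catastrophe, ≈ GTP-tubulin off-rate) and fast
  depolymerization rates in µm/min and subunits/s.
* **Plus-end structure** — Gaussian-survival fits
  *I(x) = b + A·S((x−µ)/σ)* of the tip fluorescence decay; σ is the
  *tip SD*, a proxy for the axial extent of the tapered end, binned by
  concurrent polymerization rate.
* **Live-cell dynamics** — the three-rule event criterion for astral
  microtubules (≥3 contiguous points, ΔL ≥ 0.5 µm, R² ≥ 0.80),
  catastrophe/rescue frequencies per microtubule
  (events / (lifetime − time in opposing phase)), pooled condition tables
  with order-statistic 95% CIs, Mann–Whitney and Fisher comparisons.
* **Culture assays** — doubling times from the maximal log-linear window of
  OD600 curves, normalized ratios, and scored proportions with
  SE = √(p(1−p)/n).
* **Synthetic data** — an event-exact two-state simulator (velocities
  *v<sub>g</sub>*, *v<sub>s</sub>*; hazards *f<sub>cat</sub>*,
  *f<sub>res</sub>*) and a TIRF renderer (Gaussian-survival tips, analytic
  PSF convolution, Poisson + read noise), so every stage above is
  validated by parameter recovery with known ground truth.

The methods vignette (`vignettes/mtdi-methods.Rmd`) documents the models,
estimator conventions, defaults, and known limitations.

## Worked example: one washout experiment

```r
library(mtdi)

pre   <- di_params(v_grow_um_min = 1.2, v_shrink_um_min = 0,
                   f_cat_per_min = 0, f_res_per_min = 0)
proto <- washout_protocol(t_washout_s = 30, delay_s = 20,
                          v_slow_um_min = 1.2, v_fast_um_min = 18.41)
sim <- simulate_washout_trace(pre, proto, duration_s = 120, dt_s = 1,
                              rng_seed = 11, noise_sd_um = 0.02,
                              initial_length_um = 3)
res <- analyze_washout(sim$trace, sim$background,
                       analysis_config(frame_interval_s = 1))
```

selected fields of `res`:

```
t_init_s               = 31      # washout detected 1 s after the drop starts
prewashout_rate_um_min = 0.95    # OLS over the 10 s before washout (true 1.2)
t_cat_s                = 48      # first 5-point window steeper than -150 nm/s,
delay_s                = 17      #   reported at the window's first frame (true 50/20)
slow_rate_subunits_s   = 34.09   # pre-catastrophe off-rate (true 35)
fast_rate_subunits_s   = 490.85  # biased low by the early anchor; see below
```

Phase segmentation measures the fast rate within the detected event instead
(100 nm/s shrinkage threshold so that slow depolymerizers also qualify):

```r
ev <- segment_phases(sim$trace, phase_cfg(min_slope_shrink_nm_s = 100))
to_subunits_per_s(max(ev$rate_um_min[ev$kind == "shrinkage"]))
#> 542.7   # true 18.41 um/min = 537 subunits/s
```

Over a 200-trace cohort the median slow and fast rates recover
35 and 537 subunits/s to within ~1%.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on simulated
cohorts and write tables under `results/`:

```
01_simulate_cohorts.R   traces, a two-channel TIFF movie, washouts, growth curves
02_imaging_pipeline.R   movie -> registration -> kymograph -> tracked trace (+ recovery)
03_invitro_rates.R      concentration series -> on-rate constants, catastrophe CDF
04_washout.R            washout cohorts -> delay/slow/fast + proportions + tests
05_tip_structure.R      rendered tapers -> tip SD fits binned by rate
06_invivo_dynamics.R    astral cohorts -> condition table + rank-sum tests
07_growth_assays.R      OD600 fits -> doubling times; scoring proportions
```

Each takes ~seconds and records a manifest (config, seed, input hashes).

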