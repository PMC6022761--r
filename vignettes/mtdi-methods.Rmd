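---
title: "Quantifying microtubule dynamic instability with mtdi: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microtubule dynamic instability with mtdi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtdi)
```

# The biological problem

Microtubules are polymers of alpha/beta-tubulin dimers that switch
stochastically between persistent growth and rapid shrinkage ("dynamic
instability"). The growth-to-shrinkage switch is a *catastrophe*, the
reverse a *rescue*. Experiments that quantify this behavior measure a small
set of numbers: polymerization and depolymerization velocities, catastrophe
and rescue frequencies, the apparent on-rate constant (the slope of growth
velocity against free-tubulin concentration, converted to subunits per
micromolar per second), the off-rate in the absence of free tubulin
(tubulin-washout assays), and the axial extent of the tapered plus end
("tip SD").

`mtdi` implements the full computational chain for such experiments — from
two-channel TIRF movies to kymographs to length traces to rates and
frequencies, plus the washout, tip-taper, live-cell, and culture-growth
analyses — together with a synthetic-data generator whose ground truth makes
every stage testable by parameter recovery. No stage requires real data;
every number the pipeline produces can be checked against the parameters
that generated its input.

# The two-state simulator

`simulate_length_trace()` implements the minimal dynamic-instability model:
constant growth velocity $v_g$ with catastrophe hazard $f_{cat}$, constant
shrinkage speed $v_s$ with rescue hazard $f_{res}$. Dwell times are
exponential (the process is memoryless), and switching is simulated
event-exactly before sampling at the acquisition interval, so the sampled
trace is a linear interpolation of the true piecewise-linear path. This
matches exactly the quantities the downstream estimators report — velocities
and first-order switching frequencies — and deliberately omits GTP-cap aging,
pauses, and length-dependent catastrophe: the reported summary statistics
contain no information that would constrain those refinements.

Two checks pin the simulator to theory: the fraction of time spent growing
converges to $f_{res}/(f_{cat}+f_{res})$ (the stationary distribution of
the two-state chain), and the length at first catastrophe is exponential
with rate $f_{cat}/v_g$, which the empirical CDF from
`catastrophe_length_cdf()` reproduces.

**Boundary behavior.** When a microtubule depolymerizes back to its seed,
the default is hold-and-regrow (growth resumes immediately; the rescue
hazard does not act at the seed), with `renucleate = FALSE` available to
terminate instead. In vitro, GMPCPP seeds re-nucleate; which convention is
used matters only for statistics that count events near zero length, and
both are available so the sensitivity can be measured.

**Measurement noise** is additive Gaussian on length, clamped at zero.
Defaults chosen once for the study conditions: 20 nm for washout-style
traces (sub-pixel at 65-nm pixels, tracking at 1-s frames), 50 nm for
live-cell astral-microtubule traces (spinning-disk, maximum-intensity
projections). The in vitro concentration-series analysis uses 5 nm because
kymograph event endpoints are read from line fits spanning many frames, not
from single-frame thresholding.

# Image formation and the imaging pipeline

`render_kymograph()`/`render_movie()` build TIRF-like images analytically:
the axial intensity of a microtubule whose plus end tapers with SD
$\sigma_{tip}$ is amplitude times the standard Gaussian survival function
$S((x - x_{tip})/\sigma_{tip})$; convolution with a Gaussian PSF of SD
$\sigma_{psf}$ yields the same form with
$\sigma_{eff} = \sqrt{\sigma_{tip}^2 + \sigma_{psf}^2}$, so profiles are
exact at pixel centers with no numerical convolution. Defaults: 65-nm
pixels, 130-nm PSF SD (1.49 NA objective), Poisson shot noise plus Gaussian
read noise. The seed is rendered into a separate (fiducial, immobile)
channel.

The analysis direction mirrors the standard kymograph workflow:

* `detect_seeds()` — Otsu threshold, connected components (EBImage), PCA
  axis angle. Endpoints are refined to the subpixel half-maximum crossings
  of the axial profile: a PSF-blurred edge lies at half-max, so thresholded
  extents, which overshoot by the blur, are pulled back to the true edge.
  Without this refinement tracked lengths carry a systematic ~1-2 px bias.
* `register_frames()` — Fourier cross-correlation against the first frame
  with matrix-multiply DFT upsampling for subpixel shifts. The spectrum
  keeps its energy weighting by default; the classical phase-only
  ("whitened") variant is available but is unstable when shot noise
  dominates the high frequencies, which is the regime of real TIRF data.
* `build_kymograph()` — per frame, bilinear resampling along the seed axis
  (equivalent to rotating the axis horizontal), a crop of 4 pixels above
  and below the axis, and a max-projection to one line; lines stack in
  time order.
* `track_length()` — whole-kymograph Otsu threshold by default (fixed and
  background + k SD alternatives); length is the distance from the seed
  end to the farthest contiguous above-threshold pixel, where a run of two
  or more below-threshold pixels terminates the microtubule (speckle
  guard). The plus end is chosen as the end with the larger net length
  change unless overridden.

On noiseless renders the full chain (simulate, render, register, build,
track) recovers the input trace with RMS error below one pixel; individual
frames can be off by up to ~1.5 px from the combination of threshold-edge
offset and pixel quantization, which is the natural resolution of
threshold-based tracking.

# Phase segmentation and rate estimation (in vitro)

`segment_phases()` classifies each frame by the slope of a centered
5-frame OLS regression: growth above +0.1 um/min, shrinkage below
-150 nm/s by default, neither otherwise; maximal runs of one class become
events and per-event rates use the first and last points (change in length
over change in time, times 60). Three boundary refinements remove known
digitization artifacts, each verifiable on constructed traces:

* runs are extended over unlabeled frames to the adjacent extremum while
  steps remain full-sized and sign-consistent (the centered window blurs
  changepoints by ~2 frames);
* runs are trimmed to their extrema (a phase runs peak-to-trough);
* boundary frames holding only a partial step — a mid-frame switch or
  arrival at the seed — are dropped (iteratively below half the phase's
  median step, then once below 0.9 of it). Removing a *full* step leaves a
  first-to-last rate unbiased, because the remaining intervals still
  average the true velocity; keeping a *partial* interval biases it low.

With these conventions a noiseless trace that grows at 1.2 um/min for 60 s
and then shrinks at 8.57 um/min yields exactly two events with exactly
those rates. One caveat is inherited from the defaults: the 150 nm/s
shrinkage threshold (the washout catastrophe criterion, about two pixels
per second) sits *above* 8.57 um/min = 142.8 nm/s, so segmenting
depolymerization that slow requires lowering `min_slope_shrink_nm_s`
(the analyses here use 100 nm/s, above all slow-phase and noise slopes and
below both fast rates under study).

Rates convert to subunit fluxes via the 14-protofilament lattice constant:
1750 dimers per micrometer (14 x 1000/8 nm), divided by 60 for per-second
units. `fit_rate_vs_concentration()` pools event-level points into an OLS
line (the per-concentration means with t-based 95% CIs are also reported);
its slope times 1750/60 is the apparent on-rate constant, and its
x-intercept the apparent critical concentration. Event-level pooling was
chosen over weighting per-concentration means because event counts per
concentration are unequal and the event is the natural observation unit.

At velocities whose per-frame step is comparable to the measurement noise,
threshold-selected events overestimate rates (selection on noisy extrema);
this is a property of event-calling itself, visible in the generator
round-trips, and is why the concentration-series defaults assume sub-pixel
endpoint precision.

# Washout analysis

The washout experiment removes free tubulin during imaging (1-s frames);
the plus end then depolymerizes slowly (GTP-tubulin dissociation) until
catastrophe, then fast. The analysis chain:

* `detect_washout()` — washout initiation is the first background sample
  more than $k\sigma$ (default $k = 3$; $\sigma$ = robust SD of background
  steps) below the mean of the previous three samples, confirmed at the
  next sample so an isolated spike cannot trigger it; termination is the
  first subsequent sample no longer significantly above the mean of its
  next three (the drop has finished). On a 5-s linear drop with unit noise
  the recovered duration is 5 +/- 1 s.
* `prewashout_rate()` — OLS slope over the 10 s before initiation.
* `detect_catastrophe()` — 5-point windows slide forward from washout; the
  catastrophe is the first window with OLS slope below -150 nm/s, reported
  at the window's *first* frame. First-frame anchoring makes the reported
  time up to ~2 frames early (the first qualifying window begins before
  the true switch once two of its four intervals are fast), which keeps
  the slow-phase regression uncontaminated by fast frames — the property
  that matters for the slow-rate estimate. Center/last anchoring is
  available for sensitivity analysis; recovered delays are accurate to
  about 3 frames by convention, not 1.
* `phase_rates()` — OLS slopes over washout-to-catastrophe (slow) and
  catastrophe-to-seed (fast), the latter excluding the first at-seed frame
  (the length is clamped there). Slow rates are absent when catastrophe
  coincides with washout, and exact zeros are flagged and excluded from
  slow-rate summaries.
* `summarize_washouts()` — fraction without a slow phase with the standard
  error of the proportion $\sqrt{p(1-p)/n}$, and medians with
  order-statistic (binomial) 95% CIs.

On simulated cohorts (200 traces, 20-nm noise) the pipeline recovers median
fast rates of ~537 and ~250 subunits/s from ground truths of 18.41 and
8.57 um/min, and a median slow rate of ~35 subunits/s from 1.2 um/min —
the round trip that the acceptance analysis reports.

# Tip structure

`fit_tip_profile()` fits $I(x) = b + A\,S((x-\mu)/\sigma)$ to an axial
intensity profile by variable projection: $b$ and $A$ are linear and are
profiled out, and $(\mu, \log\sigma)$ is optimized by multi-start
Nelder-Mead. The gradient-free search keeps the blunt limit well behaved
(at $\sigma \to 0$ the $\sigma$ sensitivity saturates and
derivative-based least squares stalls or diverges), and the multi-start
removes a local minimum in which noisy profiles collapse to a step.
Initialization uses the half-max crossing of a lightly median-smoothed
profile for $\mu$ and its 16/84-percentile crossings for $\sigma$; the fit
window covers the decay adaptively (at least 3-4 initial $\sigma$ on each
side). Fits whose $\sigma$ exceeds the profile span, or whose amplitude is
nonpositive, are flagged unconverged; $\sigma$ pinned at the lower bound
(1/20 pixel) is flagged.

The fitted $\sigma$ includes the PSF in quadrature. Both the raw
$\sigma$ (default, the most literal reading of the fluorescence-decay
method) and the corrected
$\sqrt{\max(\sigma^2 - \sigma_{psf}^2, 0)}$ are reported. A blunt end
imaged with a 130-nm PSF fits $\sigma \approx 130$ nm and corrects to
~0. Single fits at SNR 5 carry ~20% statistical spread — near the
information limit of a 1D profile — so tip SD is reported as a mean over
many time points (as in rate-binned summaries, `mean_tipsd_by_rate()`,
which pairs each fit with a centered 5-frame instantaneous rate); the mean
over 40 profiles recovers the true $\sigma$ within ~1%.

# Live-cell astral-microtubule dynamics

Events in yeast length traces follow the three-rule criterion: at least 3
contiguous points, first-to-last length change of at least 0.5 um, OLS
$R^2 \ge 0.80$. `classify_events()` finds candidate phases as maximal runs
of one sign of the centered 3-point slope, trims them to their extrema,
applies the three rules to the extremum-to-extremum window, and then
applies the partial-step boundary trim only when the trimmed window still
satisfies the rules (so every emitted event satisfies them as stated).

The candidate-run construction deserves its own justification. A pure
"grow the window while $R^2$ stays above 0.80" search — the most obvious
implementation of the criterion — merges events across catastrophe-rescue
cycles: once a window is long, one switch excursion cannot pull $R^2$
below 0.8, and the slope sign does not flip while the net trend persists.
Under wild-type-like conditions (26.5 nm/s growth, 4-s frames, 50-nm
noise) that implementation recovered a median polymerization rate of
0.93 um/min against a ground truth of 1.59; the sign-run construction
recovers 1.62. Requiring a consistent local slope is therefore treated as
part of what "an event" means, with the exhaustive window-enumeration
oracle (in the test suite) confirming agreement on single-switch traces.

Counting conventions: every maximal disassembly event is one catastrophe
(it is entered from an assembly event or an unclassified interlude), and
symmetrically for rescues, except that an event beginning at the first
frame was not entered from anything. Frequencies divide counts by lifetime
minus time in the opposing phase, in minutes; unclassified gaps count
toward the lifetime and toward neither phase. Per-microtubule values are
pooled across the condition and reported as medians with order-statistic
95% CIs; conditions are compared with the Mann-Whitney test
(`rank_sum_test()`, exact for small tie-free samples) and proportions with
Fisher's exact test, both delegated to R's reference implementations and
cross-checked against enumeration oracles in the tests.

**A censoring limitation worth stating plainly.** The 0.5-um rule imposes
a detection floor: a shrinkage excursion shorter than ~11 s at 46.7 nm/s
never produces 0.5 um. With exponential dwells at wild-type-like hazards
(catastrophe 1.0/min while growing, rescue 1.67/min while shrinking) and
truncation at the nucleation site, about 40% of true shrinkage excursions
fall below the rule; measured detection on simulated cohorts is ~58%
overall (100% for excursions deeper than 0.8 um). Recovered per-microtubule
catastrophe frequencies therefore sit near 0.5-0.55/min when the true
hazard is 1.0/min. Rates are unaffected (they are measured within detected
events), and the bias shrinks as dwells lengthen relative to the detection
floor — with dwell means of 100-200 s the same pipeline recovers hazards
within ~10%. When comparing conditions analyzed identically the censoring
largely cancels, but absolute frequencies from three-rule classification
should be read as lower bounds under fast-switching conditions.

# Culture assays

`fit_doubling_time()` fits log2(OD600) against time over the maximal span
of consecutive samples with OD between 0.1 and 1.0 whose regression keeps
$R^2 \ge 0.99$ (ties broken by $R^2$); doubling time is 1/slope, exact on
noiseless lag-free curves and within ~5% at 0.005 OD noise. The lower OD
bound clears typical inoculation densities and the additive noise floor,
so lag-phase points cannot dilute the slope; log-linear fitting was chosen
over fitting raw OD to an exponential because the two coincide at the
optimum under multiplicative error, and the window rule is transparent.
Non-growers (no qualifying window) are flagged rather than fitted.
Doubling times are normalized to the reference condition as a plain ratio
of medians (the unpaired design does not license a median of per-replicate
ratios). Scoring assays reduce to proportions with
$SE = \sqrt{p(1-p)/n}$ and Fisher comparisons.

# Problem sizes and reproducibility

The bundled analyses and acceptance computations use cohorts of 100-200
simulated microtubules (washout: 200 traces at 1-s frames; live-cell: 100
ten-minute traces at 4-s frames), 1000-trace property sweeps for the
catastrophe detector, and a few hundred tip fits — sizes at which the
medians under study are stable to well under the widths of their reported
CIs. Every generator takes an integer seed and is bit-reproducible; every
output is accompanied by a manifest recording the configuration, seed, and
input hashes. The numbered scripts under `analysis/` run the stages end to
end and write their tables under `results/`.

# What passing the synthetic tests does and does not show

The generator reproduces the features the estimators rely on — piecewise
linear kinetics, exponential switching, Gaussian-survival tip profiles,
PSF blur, shot and read noise, background drops at washout, exponential
culture growth. It does not emulate microtubule crossings or bundles
(flagged as a caveat for G1 cells in live imaging), stage drift beyond
rigid translation, photobleaching, GTP-cap kinetics, or non-exponential
dwell times. Parameter recovery on these synthetics therefore validates
the estimators' correctness and their stated conventions, not their
robustness to every pathology of real microscopy data.
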