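---
title: "Forecasting biologically weighted surface UV irradiance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting biologically weighted surface UV irradiance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Supervised heliotherapy — treating skin conditions such as psoriasis by
prescribed sunbathing — needs accurate forecasts of the biologically
effective UV dose rate a patient will receive. A monitoring station
scans the solar spectrum (280–400 nm at 1-nm steps) every 10 minutes
from 05:00 to 19:00 local time; weighting each scan by a clinical
action spectrum collapses it to a single *effective irradiance* in
mW/m². The clinician needs tomorrow's (and, for course planning, the
next weeks') full diurnal profile of that quantity at the 10-min
resolution.

`uvcast` implements the complete pipeline: data cleaning, a
sequence-to-sequence recurrent forecaster, autoregressive long-horizon
prediction, and an evaluation protocol, together with a seeded
synthetic generator so every stage is testable without instrument
data.

## Data model

The within-day sampling grid is parametric (`uv_grid()`): start, end
and step define `n_slots` (85 on the default grid). All containers —
spectral scans (`uv_spectral_day`), weighted series (`uv_series`),
covariates (`uv_covariate`) — are day × slot structures on a grid, with
an explicit observation mask. Timestamps label slot starts, the grid is
closed at both ends, and files carry ISO-8601 local time without a
timezone suffix (the instrument's local time is the analysis frame).

## Preprocessing

**Action-spectrum weighting.** Effective irradiance per slot is the
rectangle-rule integral `sum(w(lambda) * E(lambda) * 1 nm)`. The
weighting table is pluggable (`action_spectrum()`, `flat_spectrum()`,
`delta_spectrum()`, `read_action_spectrum()`): the published psoriasis
clearance spectrum is not distributed with the package, so clinical use
requires supplying the table from its original sources; tests use flat,
delta and toy spectra whose integrals are computable by hand.

**Imputation** (`uv_impute()`). Surface UV has strong diurnal and
annual regularity, so each missing cell is filled with the mean of all
originally observed values among: the same day's slots within ±2 steps,
the same slot on days within ±5 calendar days, and the same slot on the
same month-day in years within ±2 (Feb 29 borrows Feb 28). Donor pools
use calendar arithmetic, so excluded years leave gaps rather than
shifting donors. Imputed cells stay flagged, are never donors, and are
recomputed from scratch on re-imputation — this makes the operation
exactly idempotent while keeping the donor pool strictly observational.
Cells with an empty pool remain missing.

**Quality filtering** (`uv_quality_filter()`). Whole days are rejected
when their profile is implausible for a clear evaluation: |sample
skewness| > 0.3, max/min ratio > 15, or a maximum outside
[150, 400] mW/m². Two choices the thresholds do not pin down:

* *Which slots enter the statistics.* We use the daylight window
  08:00–16:00 (49 slots on the default grid). Including dawn/dusk slots
  would drive the minimum towards zero and make the ratio rule fire on
  every day.
* *Which skewness estimator.* The adjusted Fisher–Pearson sample
  skewness (`e1071::skewness(type = 2)`), the common statistics-package
  default.

In the pipeline the filter is applied to validation and test years
only; training keeps all days (a `filter_training` flag exists for
experimentation).

**Input denoising** (`smooth_profile()`). Model *inputs* are smoothed
with a Savitzky–Golay filter (default window 11 slots, polynomial
order 3 — conventional values for removing single-slot spikes while
preserving the bell shape; both configurable). Training *targets* are
never smoothed: the model must learn to predict real, noisy
irradiance, and the tests audit this distinction.

**Normalization.** All UV values are divided by one global scale — the
training-set maximum — and clipped to [0, 1]. A per-day scale would
discard the day-to-day amplitude information the model has to learn.
Values from later splits may exceed the training maximum and are
clipped.

**Circular date.** Day-of-year enters as
`(sin(2*pi*d/365), cos(2*pi*d/365))` with zero-based `d`, so the
feature is continuous across New Year; 365 is used in both components
(only a common period closes the circle over a year).

**Covariate alignment** (`align_covariate()`). Optional ozone / AOD500
channels are duplicated up to the grid resolution: hourly values repeat
over the six slots of their hour, daily values over all slots.

## The forecaster

`uvnet()` fits an encoder–decoder recurrent network.

* **Encoder.** The `K` (7/14/21) previous days' smoothed, normalized
  profiles — each slot carrying the UV value, the circular-date pair
  and any covariates — are concatenated into one sequence of
  `K * n_slots` timesteps. Layer 1 is a bidirectional LSTM (the two
  directions' outputs are concatenated); layer 2 a unidirectional
  LSTM. The final cell state (and, by default, the hidden state) is
  handed to the decoder.
* **Decoder.** An LSTM initialised with the encoder state reads the
  *previous year's same-date* profile; per timestep, two dense layers
  with sigmoid activations map its output to a forecast value in
  (0, 1), denormalized to mW/m². Intuitively the network predicts
  next-day irradiance as a transformation of last year's profile,
  modulated by the recent days.
* **Dropout** (rate 0.2, training only) is applied to the decoder LSTM
  output and after the first dense layer — i.e. before each dense
  layer. Placing dropout *after* the final one-unit output layer would
  randomly zero whole predictions, which no reasonable reading of the
  architecture intends.
* **Loss.** The asymmetric quantile (pinball) loss
  `mean(max(q*(yhat-y), (q-1)*(yhat-y)))` with `q = 0.33`: an
  under-forecast (too little predicted UV leads to an over-long
  prescribed session and sunburn risk) costs `(1-q)/q ≈ 2` times more
  than an over-forecast. At the kink the `q`-side subgradient is used;
  any consistent choice is valid for a piecewise-linear loss.
* **Training.** ADAM with a linearly decaying learning rate
  (`lr_init - epoch * lr_decay`; reference schedule 5e-4 and 1e-7 over
  2000 epochs at batch 256). When validation targets are supplied the
  best-validation-loss parameters are retained over the full epoch
  budget — the role of the validation year is to decide which epoch's
  weights to keep. All randomness (initialisation, shuffling, dropout)
  derives from one seed; runs are bit-reproducible.

The network, backpropagation through time and the optimiser are
implemented in vectorised base R; the analytic gradients are verified
against central finite differences in the test suite. Layer widths
default to 128 (bidirectional) and 256 with a 160-unit dense layer, and
are configurable — published sources for this architecture do not pin
the widths, so no particular parameter count is treated as normative.

## Forecasting and evaluation

`forecast_next_day()` rebuilds the input window from observed history
and runs the network in inference mode (deterministic).
`forecast_autoregressive()` forecasts `N` days by feeding each
forecast back as input for the next step — previous-year decoder
inputs always come from real data — and records, per step, which input
days were observations and which prior forecasts. Within horizons
shorter than about eleven months this also guarantees donors are never
forecasts. `baseline_previous_day()` is the persistence reference.

`uv_mape()` reports `100 * mean(|yhat-y|/y)` pooled over all
(day, slot) terms in the daylight window 08:00–16:00 (inclusive;
49 slots), where irradiance is bounded away from zero. Terms whose
true value falls below 1 mW/m² are excluded and counted, which makes
the statistic defined for arbitrary inputs; a per-day-first average is
available as an option. Breakdowns: per hour (the six slots of each
hour; 16:00 forms its own terminal group) and, given a daily cloud
covariate, per 0.1-wide coverage bin plus the Spearman rank correlation
between per-day MAPE and coverage.

## The synthetic generator

`uv_simulate()` emulates the statistical structure the method relies
on, not any station's climatology:

* clear-sky profile: seasonal daily peak
  `P(d) = 300 + 60 * cos(2*pi*(d - 105)/365)` mW/m² times a Gaussian
  diurnal bell centred at noon;
* multiplicative cloud attenuation `1 - 0.75 * c_d` with daily coverage
  `c_d` following a seasonal mean (base 0.30, amplitude 0.15, peak at
  day 255) plus independent Gaussian noise (sd 0.15), clipped to
  [0, 1] — full overcast removing 75 % of clear-sky UV is a fixed
  structural choice, not a radiative-transfer result;
* occasional multiplicative spikes (×2–5 on single slots) to exercise
  the denoising path, and multi-day missing blocks to exercise
  imputation.

The diurnal bell width defaults to 2.0 h. This value matters: the
daylight-window sample skewness of a Gaussian bell depends on its
width, and at 2.0 h a clear day sits comfortably inside all quality
thresholds (skewness ≈ −0.06, ratio ≈ 7), whereas a 3-h bell would be
rejected by the skewness rule on every day — a generator whose own
clean output fails the filter would be useless for testing. What the
generator does *not* emulate: solar-zenith-angle geometry, spectrally
resolved physics, autocorrelated weather fronts, aerosol trends.
Passing tests therefore demonstrate the pipeline's mechanics and the
forecaster's ability to exploit seasonal structure with independent
daily noise — not performance on any real station's data.

`make_fixture_suite()` writes a deterministic CSV fixture set — three
clean years, a year with two 4-day gaps whose donors exist by
construction, twenty day-profiles of which exactly five violate
specific quality rules, toy spectra — with a JSON manifest of expected
outcomes.

## Numerical and design choices

* Analytic BPTT gradients, checked against central differences at
  tolerance 1e-3 (relative, away from the loss kink).
* Forget-gate biases initialise at 1; other weights uniform in
  ±1/sqrt(fan-in).
* Previous-year donor lookup: same month-day one year back, then two
  years back, then the climatological per-slot mean of earlier years'
  same month-day; never future data.
* Window eligibility is pure calendar arithmetic: a target needs `K`
  complete days immediately before the forecast lead and a donor;
  histories may cross year boundaries.
* The "forecast specific date" variant (training targets shifted `h`
  days ahead) is the `lead` parameter, not a separate model class.
* Empty-split, all-rejected, missing-history and non-finite-loss
  conditions fail loudly with named diagnostics.

## Problem sizes in the test suite

The reference configuration (85 slots, widths 128/256, 2000 epochs) is
not exercised in tests; the architecture and grid are parametric, and
tests scale them down so the full suite runs on one CPU in minutes:
hourly or 30-min grids (15/29 slots), widths 4–24, and short ADAM
schedules with a correspondingly larger initial rate (0.01 with decay
1e-5 over 150 epochs for the skill study; the reference 5e-4/1e-7
schedule is used where the test is about the schedule itself). The
skill study trains on every second day of two target years — three
years of history — and evaluates next-day forecasts on a held-out
fourth year against the previous-day baseline across five seeds.

## Limitations

* The package ships no clinical action spectrum; users must supply one.
* Pure-R training is CPU-bound: the full-scale reference configuration
  is feasible but slow; the package is written for methodological
  fidelity and testability first.
* The synthetic generator's independence assumptions (day-to-day cloud
  noise) flatter a forecaster that learns seasonal means; real skill on
  a station requires retraining and evaluation on that station's data.
* Quality-filter thresholds are calibrated for mid-latitude/tropical
  antipsoriatic irradiance scales; other action spectra or sites need
  rescaled ceilings and floors.
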