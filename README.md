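# uvcast

Forecasting biologically weighted surface ultraviolet irradiance for
heliotherapy planning.

Supervised sunbathing (heliotherapy) is an effective treatment for
psoriasis and other skin conditions where hospital phototherapy is out
of reach, but prescribing a safe session length requires knowing
tomorrow's biologically effective UV dose rate — the solar spectrum
`E(lambda)` (280–400 nm) weighted by a clinical action spectrum
`w(lambda)`:

    F(t) = sum over lambda of w(lambda) * E(lambda, t) * 1 nm   [mW/m^2]

`uvcast` provides the full pipeline around a sequence-to-sequence
recurrent forecaster of the daily profile `F(t)` on a 10-min grid
(05:00–19:00, 85 slots by default):

* **I/O** for spectral scans, weighted series, covariates and action
  spectra (plain CSV contracts), with pluggable weighting tables.
* **Cleaning**: seasonal calendar-window imputation (±2 slots, ±5 days,
  ±2 years), day-profile quality filtering (skewness / max-min ratio /
  range rules), Savitzky–Golay denoising of model inputs (never of
  training targets), [0, 1] normalization by the training maximum.
* **Model**: a bidirectional-LSTM encoder reads the past `K` days
  (7/14/21) as one sequence and hands its final cell state to an LSTM
  decoder that reads *last year's same-date* profile; two sigmoid dense
  layers (dropout 0.2) emit one value per slot. Training minimises the
  asymmetric quantile (pinball) loss

      L = mean( max( q * (yhat - y), (q - 1) * (yhat - y) ) ),  q = 0.33,

  so under-forecasts — which would prescribe over-long sessions and risk
  sunburn — cost about twice as much as over-forecasts. Optimisation is
  ADAM with a linearly decaying learning rate; the network,
  backpropagation through time and the optimiser are implemented in
  vectorised base R and gradient-checked against finite differences.
* **Forecasting**: deterministic next-day prediction, autoregressive
  multi-week horizons (each forecast fed back as input, with per-step
  provenance), and a previous-day persistence baseline.
* **Evaluation**: MAPE over the 08:00–16:00 daylight window, broken down
  by hour and by cloud-coverage bin with a Spearman rank correlation.
* **Synthetic data**: a seeded generator (seasonal clear-sky cycle,
  Gaussian diurnal bell, multiplicative cloud attenuation with
  independent daily noise, spikes, missing blocks) plus a deterministic
  fixture suite, so everything is testable without instrument data.

## Worked example

Fit a compact forecaster on three years of synthetic data (hourly grid)
and evaluate the second half of the final year against persistence,
quality-filtering the evaluation days as the protocol prescribes:

```r
library(uvcast)
sim <- uv_simulate(n_years = 3, start_year = 2019,
                   grid = uv_grid(step = 60), spike_rate = 0, seed = 42)
series <- uv_impute(sim$series)
fit <- uvnet(series, K = 7,
             targets = seq(as.Date("2020-01-01"), as.Date("2021-06-30"),
                           by = "2 days"),
             control = uvnet_control(encoder_hidden = c(8, 12),
                                     dense_hidden = 12,
                                     smoothing_window = 5,
                                     smoothing_polyorder = 2),
             training = uvnet_training(lr_init = 0.01, lr_decay = 1e-5,
                                       epochs = 150),
             seed = 1)
print(fit)
#> Sequence-to-sequence UV irradiance forecaster
#>   encoder: BiLSTM(8) -> LSTM(12); decoder: LSTM(12) -> dense(12) -> dense(1)
#>   K = 7 past days, lead = 1, quantile q = 0.33, dropout = 0.2
#>   trained on 274 windows for 150 epochs (seed 1); scale = 359.991 mW/m2
#>   final training loss 0.01978

fc <- predict(fit, series, dates = as.Date("2021-08-15"))
round(fc$values[1, c("08:00", "10:00", "12:00", "14:00", "16:00")], 1)
#> 08:00 10:00 12:00 14:00 16:00
#>  24.0 116.7 175.7 112.6  19.1
```

The forecast is a full diurnal profile in mW/m² — the bell shape a
clinician would convert into a session dose. Evaluating every
quality-retained day of Jul–Dec 2021:

```r
test_window <- series[which(series$dates >= as.Date("2021-07-01"))]
keep <- uv_quality_filter(test_window)$series$dates
keep <- keep[keep <= as.Date("2021-12-30")]
uv_mape(forecast_next_day(fit, series, keep), series)
#> <uv_eval> MAPE 15.77% over 148 day(s), 1332 terms (08:00-16:00, 0 excluded)
uv_mape(baseline_previous_day(series, keep), series)$mape_overall
#> 15.85
```

So even this deliberately small model edges out the previous-day
baseline on a half year of held-out days; the scaled study in
`scripts/acceptance.R` (a full test year, five seeds in the test suite)
shows the ordering more clearly. MAPE in the 10–25 % range is the
accuracy band phototherapy dosimetry guidelines consider acceptable.

A command-line pipeline (`simulate | prepare | train | forecast |
evaluate`) is available via `inst/cli/uvcast.R` with a YAML
configuration (`inst/extdata/example-config.yaml`).

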