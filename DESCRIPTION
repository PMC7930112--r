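Package: uvcast
Title: Surface Ultraviolet Irradiance Forecasting with a Recurrent
    Encoder-Decoder Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forecasts biologically weighted surface ultraviolet (UV)
    irradiance for heliotherapy and photodermatology planning.  Provides
    readers and writers for spectral and broadband irradiance time series,
    action-spectrum weighting of 280-400 nm spectra, seasonal
    calendar-window imputation of missing records, day-profile quality
    filtering, Savitzky-Golay input denoising, a sequence-to-sequence LSTM
    forecaster trained with an asymmetric quantile (pinball) loss,
    autoregressive multi-day forecasting, a previous-day persistence
    baseline, mean-absolute-percentage-error evaluation stratified by hour
    and by cloud cover, and a seeded synthetic-data generator so that the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
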