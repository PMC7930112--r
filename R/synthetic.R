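#' Seeded synthetic surface-UV generator
#'
#' Generates weighted-irradiance series with the statistical structure
#' the forecaster assumes, so the whole pipeline is testable without
#' instrument data: an annual seasonal cycle of daily peak irradiance, a
#' Gaussian diurnal bell peaking at solar noon, a seasonally varying
#' multiplicative cloud-attenuation process with independent day-to-day
#' variability, occasional multiplicative noise spikes on single slots,
#' and multi-day missing blocks.
#'
#' Clear-sky value at day `d`, slot `s`:
#' `P(d) * exp(-(t_s - 12h)^2 / (2 * diurnal_width^2))` with
#' `P(d) = peak_mean + peak_seasonal_amplitude * cos(2*pi*(d - peak_phase_day)/365)`.
#' Daily cloud coverage:
#' `c_d = clip(cloud_base + cloud_amplitude * cos(2*pi*(d - cloud_phase_day)/365) + N(0, cloud_daily_sd), 0, 1)`,
#' and the observed value is `clear_sky * (1 - 0.75 * c_d)` (full overcast
#' removes 75% of clear-sky UV — a fixed structural choice, not a
#' radiative-transfer model).  Everything is reproducible from `seed`.
#'
#' @param n_years Number of calendar years to generate.
#' @param start_year First calendar year.
#' @param grid A [uv_grid()].
#' @param peak_mean,peak_seasonal_amplitude Mean and seasonal amplitude of
#'   the clear-sky daily peak (mW/m2).
#' @param peak_phase_day Day of year of the annual clear-sky maximum.
#' @param diurnal_width Bell spread in hours.
#' @param cloud_base,cloud_amplitude,cloud_phase_day Seasonal mean cloud
#'   coverage parameters (coverage in \[0, 1\]).
#' @param cloud_daily_sd Day-to-day Gaussian variability of coverage.
#' @param cloud_attenuation Fraction of clear-sky UV removed at full
#'   overcast.
#' @param spike_rate Per-slot probability of a multiplicative noise spike.
#' @param spike_range Range of the multiplicative spike factor.
#' @param missing_block_rate Per-day probability that a missing block
#'   starts.
#' @param missing_block_len Inclusive range of missing-block lengths in
#'   days.
#' @param seed Integer seed.
#' @return A list of class `uv_sim`: `series` (observed [uv_series()] with
#'   missing mask), `clear_sky` (noise-free reference), `cloud` (daily
#'   coverage [uv_covariate()]), and the configuration.  With
#'   `spike_rate = 0` the series never exceeds `clear_sky` where observed.
#' @export
uv_simulate <- function(n_years = 3, start_year = 2011, grid = uv_grid(),
                        peak_mean = 300, peak_seasonal_amplitude = 60,
                        peak_phase_day = 105, diurnal_width = 2.0,
                        cloud_base = 0.30, cloud_amplitude = 0.15,
                        cloud_phase_day = 255, cloud_daily_sd = 0.15,
                        cloud_attenuation = 0.75,
                        spike_rate = 0.002, spike_range = c(2, 5),
                        missing_block_rate = 0.01,
                        missing_block_len = c(2, 5), seed = 1) {
  if (peak_seasonal_amplitude < 0 || peak_mean <= peak_seasonal_amplitude) {
    stop("need peak_mean > peak_seasonal_amplitude >= 0")
  }
  for (p in c(spike_rate, missing_block_rate, cloud_base)) {
    if (p < 0 || p > 1) stop("rates and coverages must lie in [0, 1]")
  }
  dates <- seq(as.Date(sprintf("%04d-01-01", start_year)),
               as.Date(sprintf("%04d-12-31", start_year + n_years - 1)),
               by = "day")
  nd <- length(dates)
  doy <- day_of_year(dates)
  t_h <- grid$slot_min / 60
  bell <- exp(-(t_h - 12)^2 / (2 * diurnal_width^2))
  peak <- peak_mean +
    peak_seasonal_amplitude * cos(2 * pi * (doy - peak_phase_day) / 365)
  clear <- outer(peak, bell)

  out <- with_seed(seed, {
    cloud <- pmin(pmax(cloud_base +
                         cloud_amplitude * cos(2 * pi * (doy - cloud_phase_day) / 365) +
                         stats::rnorm(nd, 0, cloud_daily_sd), 0), 1)
    vals <- clear * (1 - cloud_attenuation * cloud)
    if (spike_rate > 0) {
      hit <- matrix(stats::runif(nd * grid$n_slots) < spike_rate,
                    nd, grid$n_slots)
      fac <- matrix(stats::runif(nd * grid$n_slots, spike_range[1],
                                 spike_range[2]), nd, grid$n_slots)
      vals[hit] <- vals[hit] * fac[hit]
    }
    miss_day <- rep(FALSE, nd)
    if (missing_block_rate > 0) {
      starts <- which(stats::runif(nd) < missing_block_rate)
      len_choices <- missing_block_len[1]:missing_block_len[2]
      for (s in starts) {
        len <- len_choices[sample.int(length(len_choices), 1)]
        miss_day[s:min(s + len - 1, nd)] <- TRUE
      }
    }
    vals[miss_day, ] <- NA_real_
    list(vals = vals, cloud = cloud)
  })

  structure(
    list(series = uv_series(out$vals, dates, grid, label = "synthetic"),
         clear_sky = uv_series(clear, dates, grid, label = "clear-sky"),
         cloud = uv_covariate("cloud", dates, rep(NA_integer_, nd),
                              out$cloud, resolution = "daily"),
         config = list(n_years = n_years, start_year = start_year,
                       peak_mean = peak_mean,
                       peak_seasonal_amplitude = peak_seasonal_amplitude,
                       peak_phase_day = peak_phase_day,
                       diurnal_width = diurnal_width,
                       cloud_base = cloud_base,
                       cloud_amplitude = cloud_amplitude,
                       cloud_phase_day = cloud_phase_day,
                       cloud_daily_sd = cloud_daily_sd,
                       cloud_attenuation = cloud_attenuation,
                       spike_rate = spike_rate, spike_range = spike_range,
                       missing_block_rate = missing_block_rate,
                       missing_block_len = missing_block_len, seed = seed)),
    class = "uv_sim"
  )
}

#' @export
print.uv_sim <- function(x, ...) {
  cat(sprintf("<uv_sim> %d day(s) (%d missing), seed %d\n",
              nrow(x$series$values), sum(!x$series$observed[, 1]),
              x$config$seed))
  invisible(x)
}

#' Toy spectral decomposition of a series
#'
#' Expands a weighted series into 5-wavelength toy spectra whose weighted
#' sum under the returned action spectrum reproduces the series exactly
#' (the per-wavelength shape is flat and the weights sum to 1 per nm).
#'
#' @param series A [uv_series()].
#' @return List with `days` (list of `uv_spectral_day`) and `spectrum`
#'   (the matching [action_spectrum()]).
#' @export
toy_spectra <- function(series) {
  wls <- c(300, 310, 320, 330, 340)
  wts <- c(0.1, 0.2, 0.4, 0.2, 0.1)   # sums to 1 per 1-nm rectangle rule
  days <- lapply(seq_along(series$dates), function(i) {
    spectra <- matrix(series$values[i, ], series$grid$n_slots, length(wls),
                      dimnames = list(slot_labels(series$grid), wls))
    structure(list(date = series$dates[i], wavelengths = wls,
                   spectra = spectra, observed = series$observed[i, ],
                   grid = series$grid),
              class = "uv_spectral_day")
  })
  list(days = days, spectrum = action_spectrum(wls, wts, "toy"))
}

# Gaussian bell profile on a grid (peak at `mu` hours, spread `sd` hours).
bell_profile <- function(grid, peak, mu = 12, sd = 2.0, offset = 0) {
  t_h <- grid$slot_min / 60
  offset + peak * exp(-(t_h - mu)^2 / (2 * sd^2))
}

#' Write the deterministic test-fixture suite
#'
#' Writes a small, fully deterministic set of CSV fixtures plus a JSON
#' manifest of expected outcomes: three clean years; one year with two
#' 4-day missing blocks (all imputable by construction); twenty
#' day-profiles of which exactly five violate the quality rules (one
#' skewed, one disproportional, two above the ceiling, one below the
#' floor) by construction; and a toy spectral file with its action
#' spectrum.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return The manifest (also written to `manifest.json`), invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- uv_grid()
  path <- function(f) file.path(out_dir, f)

  # 1. three clean years (cloud variability, no spikes, no gaps)
  clean <- uv_simulate(n_years = 3, start_year = 2011, grid = grid,
                       spike_rate = 0, missing_block_rate = 0, seed = seed)
  write_series_csv(clean$series, path("clean3y.csv"))
  write_covariate_csv(clean$cloud, path("clean3y_cloud.csv"))

  # 2. one year with two 4-day missing blocks (days 100-103 and 200-203)
  oneyr <- uv_simulate(n_years = 1, start_year = 2014, grid = grid,
                       spike_rate = 0, missing_block_rate = 0,
                       seed = seed + 1)
  vals <- oneyr$series$values
  block_days <- c(100:103, 200:203)
  vals[block_days, ] <- NA_real_
  gaps <- uv_series(vals, oneyr$series$dates, grid, label = "synthetic")
  write_series_csv(gaps, path("missing_blocks.csv"))

  # 3. twenty day-profiles, five violating the quality rules
  profiles <- rbind(
    t(vapply(seq_len(15), function(i) {
      bell_profile(grid, 200 + 12 * i)        # 212..380, all rules pass
    }, numeric(grid$n_slots))),
    bell_profile(grid, 240, mu = 10, sd = 2.5, offset = 60),  # skewness
    bell_profile(grid, 300, sd = 1.6),                        # ratio > 15
    bell_profile(grid, 450),                                  # ceiling
    bell_profile(grid, 420),                                  # ceiling
    bell_profile(grid, 120)                                   # floor
  )
  qdates <- as.Date("2015-03-01") + 0:19
  quality <- uv_series(profiles, qdates, grid, label = "quality-fixture")
  write_series_csv(quality, path("quality20.csv"))

  # 4. toy spectral day + matching action spectrum
  spec <- toy_spectra(clean$series[1])
  sd1 <- spec$days[[1]]
  lines <- "datetime,wavelength_nm,irradiance_mw_m2_nm"
  for (s in which(sd1$observed)) {
    lines <- c(lines, sprintf("%s,%s,%s",
                              fmt_datetime(sd1$date, grid$slot_min[s]),
                              fmt_num(sd1$wavelengths),
                              fmt_num(sd1$spectra[s, ])))
  }
  writeLines(lines, path("spectral_toy.csv"))
  writeLines(c("wavelength_nm,weight",
               sprintf("%s,%s", fmt_num(spec$spectrum$wavelengths),
                       fmt_num(spec$spectrum$weights))),
             path("toy_action_spectrum.csv"))

  manifest <- list(
    seed = seed,
    files = list(
      clean3y = list(file = "clean3y.csv", n_days = nrow(clean$series$values),
                     n_missing_days = 0),
      clean3y_cloud = list(file = "clean3y_cloud.csv"),
      missing_blocks = list(file = "missing_blocks.csv",
                            n_days = 365, n_missing_days = 8,
                            missing_dates = as.character(
                              oneyr$series$dates[block_days]),
                            expect_imputable = TRUE),
      quality20 = list(file = "quality20.csv", n_days = 20,
                       expect_rejected = list(
                         list(date = as.character(qdates[16]),
                              rules = "skewness"),
                         list(date = as.character(qdates[17]),
                              rules = "ratio"),
                         list(date = as.character(qdates[18]),
                              rules = "ceiling"),
                         list(date = as.character(qdates[19]),
                              rules = "ceiling"),
                         list(date = as.character(qdates[20]),
                              rules = "floor"))),
      spectral_toy = list(file = "spectral_toy.csv",
                          action_spectrum = "toy_action_spectrum.csv",
                          weighted_equals = "first day of clean3y.csv")
    )
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
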