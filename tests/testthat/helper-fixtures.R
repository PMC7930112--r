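# Shared fixtures.  Tests use deliberately small grids so the whole
# suite stays fast; the grid geometry is parametric throughout the
# package, so nothing depends on the full 85-slot default.

# 15-slot hourly grid spanning the default day
tiny_grid <- function() uv_grid(step = 60)

# 5-slot grid around noon, for hand-computable oracles
nano_grid <- function() uv_grid("10:00", "14:00", step = 60)

# a series with constant value per day on a given grid
const_series <- function(dates, value, grid = nano_grid()) {
  uv_series(matrix(value, length(dates), grid$n_slots),
            dates, grid)
}

# clean synthetic fixture (no spikes, no gaps) on the tiny grid
clean_sim <- function(n_years = 2, seed = 3, cloud_daily_sd = 0.15, ...) {
  uv_simulate(n_years = n_years, grid = tiny_grid(), spike_rate = 0,
              missing_block_rate = 0, cloud_daily_sd = cloud_daily_sd,
              seed = seed, ...)
}

# small fast architecture for training tests (callers may override)
tiny_control <- function(...) {
  args <- utils::modifyList(
    list(encoder_hidden = c(4, 6), dense_hidden = 6, dropout = 0,
         smoothing_window = 5, smoothing_polyorder = 2),
    list(...))
  do.call(uvnet_control, args)
}

# adjusted Fisher-Pearson sample skewness by explicit moments
moment_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  g1 <- m3 / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
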