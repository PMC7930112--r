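# one small fitted model shared across forecasting tests
fit_small_model <- function(seed = 7) {
  sim <- clean_sim(n_years = 2, seed = 51)
  targets <- seq(as.Date("2012-04-01"), by = "day", length.out = 20)
  m <- uvnet(sim$series, K = 3, targets = targets,
             control = tiny_control(),
             training = uvnet_training(epochs = 5, batch_size = 32),
             seed = seed)
  list(model = m, series = sim$series)
}

test_that("next-day forecasts have the right shape, sign and determinism", {
  fs <- fit_small_model()
  fc <- forecast_next_day(fs$model, fs$series, as.Date("2012-08-01"))
  expect_equal(dim(fc$values), c(1, fs$series$grid$n_slots))
  expect_true(all(fc$values >= 0 & fc$values <= fs$model$scale))
  fc2 <- forecast_next_day(fs$model, fs$series, as.Date("2012-08-01"))
  expect_identical(fc$values, fc2$values)
  expect_equal(fc$provenance[[1]]$source, rep("observed", 3))
})

test_that("forecasting fails loudly when history is missing", {
  fs <- fit_small_model()
  expect_error(forecast_next_day(fs$model, fs$series, as.Date("2011-01-02")),
               "2011-01-02")
})

test_that("the forecast path reuses the training window assembly", {
  fs <- fit_small_model()
  td <- as.Date("2012-09-15")
  ws <- build_windows(fs$series, K = 3, targets = td,
                      scale = fs$model$scale,
                      smoothing_window = 5, smoothing_polyorder = 2,
                      with_target = FALSE)
  st <- uvcast:::stack_windows(ws)
  manual <- uvcast:::nnet_forward(fs$model$params, st,
                                  fs$model$control)$Yhat * fs$model$scale
  fc <- forecast_next_day(fs$model, fs$series, td)
  expect_equal(fc$values[1, ], manual[1, ], ignore_attr = TRUE)
})

test_that("horizon-1 autoregression is identical to the next-day forecast", {
  fs <- fit_small_model()
  start <- as.Date("2012-07-31")
  ar <- forecast_autoregressive(fs$model, fs$series, start, 1)
  nd <- forecast_next_day(fs$model, fs$series, start + 1)
  expect_identical(ar$values[1, ], nd$values[1, ])
})

test_that("autoregressive provenance matches the bookkeeping oracle", {
  fs <- fit_small_model()
  start <- as.Date("2012-07-31")
  K <- fs$model$K
  ar <- forecast_autoregressive(fs$model, fs$series, start, 3)
  for (h in 1:3) {
    prov <- ar$provenance[[h]]
    expect_equal(prov$day, start + h - 1 - (K:1) + 1)
    # step h uses min(h-1, K) prior forecasts, the rest observations
    expect_equal(sum(prov$source == "forecast"), min(h - 1, K))
    expect_equal(prov$source == "forecast", prov$day > start)
  }
})

test_that("a 28-day autoregressive run stays within [0, scale]", {
  fs <- fit_small_model()
  ar <- forecast_autoregressive(fs$model, fs$series,
                                as.Date("2012-08-31"), 28)
  expect_equal(nrow(ar$values), 28)
  expect_true(all(ar$values >= 0 & ar$values <= fs$model$scale))
  expect_equal(ar$horizon, 1:28)
})

test_that("the persistence baseline copies the previous day exactly", {
  sim <- clean_sim(n_years = 1, seed = 52)
  s <- sim$series
  bl <- baseline_previous_day(s, as.Date("2011-06-10"))
  expect_equal(bl$values[1, ],
               s$values[s$dates == as.Date("2011-06-09"), ],
               ignore_attr = TRUE)
  expect_error(baseline_previous_day(s, as.Date("2011-01-01")), "missing")
  # constant series: baseline is perfect
  cs <- const_series(seq(as.Date("2020-06-01"), by = "day",
                         length.out = 5), 100)
  ev <- uv_mape(baseline_previous_day(cs, as.Date("2020-06-03")), cs,
                window = c("10:00", "14:00"))
  expect_equal(ev$mape_overall, 0)
})

test_that("baseline MAPE on a proportional series matches the formula", {
  g <- nano_grid()
  dates <- as.Date("2020-06-01") + 0:1
  prof <- c(100, 200, 300, 200, 100)
  s <- uv_series(rbind(prof, 1.2 * prof), dates, g)
  ev <- uv_mape(baseline_previous_day(s, dates[2]), s,
                window = c("10:00", "14:00"))
  # prediction = day1, truth = 1.2 * day1: APE = 0.2/1.2 everywhere
  expect_equal(ev$mape_overall, 100 * 0.2 / 1.2)
})

test_that("MAPE matches term-by-term enumeration on a toy case", {
  g <- nano_grid()
  dates <- as.Date("2020-06-01") + 0:1
  truth <- uv_series(rbind(c(100, 150, 200, 150, 100),
                           c(110, 160, 210, 160, 110)), dates, g)
  pred <- uv_series(rbind(c(90, 160, 190, 155, 105),
                          c(120, 150, 220, 150, 100)), dates, g,
                    label = "pred")
  fc <- structure(list(values = pred$values, dates = dates, grid = g,
                       horizon = c(1, 1), provenance = list(), scale = 1),
                  class = "uv_forecast")
  ev <- uv_mape(fc, truth, window = c("10:00", "14:00"))
  oracle <- 100 * mean(abs(pred$values - truth$values) / truth$values)
  expect_equal(ev$mape_overall, oracle)
  expect_equal(ev$n_terms, 10)
})

test_that("perfect and uniformly biased forecasts give 0 and 10 percent", {
  sim <- clean_sim(n_years = 1, seed = 53)
  s <- sim$series
  as_fc <- function(vals, dates) {
    structure(list(values = vals, dates = dates, grid = s$grid,
                   horizon = rep(1L, length(dates)), provenance = list(),
                   scale = max(s$values)), class = "uv_forecast")
  }
  dates <- s$dates[100:104]
  vals <- s$values[100:104, ]
  expect_equal(uv_mape(as_fc(vals, dates), s)$mape_overall, 0)
  expect_equal(uv_mape(as_fc(1.1 * vals, dates), s)$mape_overall, 10)
})

test_that("MAPE is scale-invariant and floors out tiny denominators", {
  sim <- clean_sim(n_years = 1, seed = 54)
  s <- sim$series
  dates <- s$dates[50:54]
  pred_vals <- s$values[50:54, ] * 1.07
  as_fc <- function(vals, dates, scale = 1) {
    structure(list(values = vals, dates = dates, grid = s$grid,
                   horizon = rep(1L, length(dates)), provenance = list(),
                   scale = scale), class = "uv_forecast")
  }
  ev1 <- uv_mape(as_fc(pred_vals, dates), s)
  s2 <- uv_series(s$values * 3, s$dates, s$grid)
  ev2 <- uv_mape(as_fc(pred_vals * 3, dates), s2)
  expect_equal(ev1$mape_overall, ev2$mape_overall)
  expect_equal(ev1$mape_by_hour, ev2$mape_by_hour)
  # a floor above the data excludes everything -> error
  expect_error(uv_mape(as_fc(pred_vals, dates), s, floor = 1e6), "no valid")
})

test_that("per-hour keys tile the evaluation window", {
  sim <- clean_sim(n_years = 1, seed = 55)
  s <- sim$series
  fc <- structure(list(values = s$values[10:11, ] * 1.05,
                       dates = s$dates[10:11], grid = s$grid,
                       horizon = c(1L, 1L), provenance = list(), scale = 1),
                  class = "uv_forecast")
  ev <- uv_mape(fc, s)
  expect_equal(names(ev$mape_by_hour),
               sprintf("%02d:00", 8:16))
  expect_equal(ev$n_terms, 2 * 9)   # hourly grid: 9 slots in 08:00-16:00
})

test_that("cloud stratification bins days and reports rank correlation", {
  sim <- clean_sim(n_years = 1, seed = 56)
  s <- sim$series
  dates <- s$dates[30:59]
  noise <- seq(1, 1.3, length.out = 30)   # error grows over the month
  vals <- s$values[30:59, ] * noise
  fc <- structure(list(values = vals, dates = dates, grid = s$grid,
                       horizon = rep(1L, 30), provenance = list(),
                       scale = 1), class = "uv_forecast")
  cloud <- uv_covariate("cloud", dates, rep(NA_integer_, 30),
                        seq(0.05, 0.95, length.out = 30))
  ev <- uv_mape(fc, s, cloud = cloud)
  expect_false(is.null(ev$mape_by_cloud_bin))
  # per-day MAPE grows exactly with coverage here
  expect_equal(ev$spearman_cloud, 1)
  expect_true(all(diff(ev$mape_by_cloud_bin) > 0))
})
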