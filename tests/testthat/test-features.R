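test_that("circular date encoding hits the cardinal points and wraps", {
  expect_equal(circular_date(1), c(sin = 0, cos = 1))
  quarter <- circular_date(1 + 365 / 4)   # d = 365/4
  expect_equal(unname(quarter), c(1, 0), tolerance = 1e-12)
  wrap <- circular_date(366)              # d = 365: full period
  expect_equal(unname(wrap), c(0, 1), tolerance = 1e-12)
  expect_error(circular_date(0), "1..366")
})

test_that("circular date output always lies on the unit circle", {
  cd <- circular_date(1:366)
  expect_equal(rowSums(cd^2), rep(1, 366), tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing preserves fitted-order polynomials", {
  x <- seq_len(41)
  expect_equal(smooth_profile(rep(7, 41), 11, 3), rep(7, 41))
  quad <- 3 + 0.5 * x - 0.02 * x^2 + 120   # keep positive
  expect_equal(smooth_profile(quad, 11, 3), quad, tolerance = 1e-9)
  cubic <- 200 + x - 0.05 * x^2 + 0.001 * x^3
  expect_equal(smooth_profile(cubic, 9, 3), cubic, tolerance = 1e-9)
})

test_that("an impulse maps to the central least-squares coefficient", {
  for (case in list(c(11, 3), c(7, 2), c(9, 4))) {
    w <- case[1]; p <- case[2]
    h <- (w - 1) / 2
    # oracle: weight of the centre sample in a local polynomial fit
    X <- outer(-h:h, 0:p, `^`)
    weights0 <- (solve(crossprod(X), t(X)))[1, ]
    n <- 41
    impulse <- rep(0, n); impulse[21] <- 1
    sm <- smooth_profile(impulse, w, p)
    expect_equal(sm[21], max(weights0[h + 1], 0), tolerance = 1e-10,
                 info = sprintf("window %d order %d", w, p))
  }
})

test_that("window 1 smoothing is the identity and negatives are clipped", {
  x <- runif(20, 0, 5)
  expect_identical(smooth_profile(x, 1, 0), x)
  spike <- c(rep(0, 10), 50, rep(0, 10))
  expect_true(all(smooth_profile(spike, 7, 2) >= 0))
  expect_error(smooth_profile(x, 21, 3), "exceed")
  expect_error(smooth_profile(x, 8, 3), "odd")
})

test_that("normalization maps the training maximum to 1 and round-trips", {
  s <- clean_sim(n_years = 1, seed = 6)$series
  ns <- uv_normalize(s)
  expect_equal(max(ns$values), 1)
  expect_true(all(ns$values >= 0 & ns$values <= 1))
  back <- uv_denormalize(ns)
  expect_equal(back$values, s$values, ignore_attr = TRUE)
  # out-of-range values under a supplied scale are clipped to 1
  clipped <- uv_normalize(s, scale = max(s$values) / 2)
  expect_equal(max(clipped$values), 1)
  expect_error(uv_normalize(s, scale = -1), "positive")
})

test_that("covariates are duplicated up to the grid resolution", {
  g <- uv_grid()
  d <- as.Date("2020-06-01")
  hourly <- uv_covariate("aod500", rep(d, 14), (5:18) * 60L,
                         seq(0.1, 1.4, by = 0.1))
  al <- align_covariate(hourly, g, d)
  in_hour <- g$slot_min >= 600 & g$slot_min < 660     # 10:00..10:50
  expect_equal(unname(al[1, in_hour]), rep(0.6, 6))   # value for 10:00
  daily <- uv_covariate("ozone", d, NA_integer_, 260)
  expect_equal(unname(align_covariate(daily, g, d)[1, ]), rep(260, 85))
  per_slot <- uv_covariate("x", rep(d, g$n_slots), g$slot_min,
                           seq_len(g$n_slots), resolution = "slot")
  expect_equal(unname(align_covariate(per_slot, g, d)[1, ]),
               as.numeric(seq_len(g$n_slots)))
  # a day with no covariate value is NA
  expect_true(all(is.na(align_covariate(daily, g, d + 1))))
})

test_that("window availability follows the calendar arithmetic", {
  sim <- clean_sim(n_years = 3, seed = 8)   # 2011-2013
  s <- sim$series
  ws <- build_windows(s, K = 7, smoothing_window = 5,
                      smoothing_polyorder = 2)
  dates <- as.Date(vapply(ws$windows, function(w) as.character(w$date),
                          character(1)))
  # donors need a previous year, and K-day histories may cross the year
  # boundary: the first eligible target is year 2, day 1
  expect_equal(min(dates), as.Date("2012-01-01"))
  expect_equal(max(dates), as.Date("2013-12-31"))
  expect_equal(length(dates), as.integer(as.Date("2013-12-31") -
                                           as.Date("2012-01-01")) + 1)
})

test_that("Feb 29 targets borrow the previous year's Feb 28 donor", {
  sim <- uv_simulate(n_years = 2, start_year = 2011, grid = tiny_grid(),
                     spike_rate = 0, missing_block_rate = 0, seed = 13)
  s <- sim$series
  ws <- build_windows(s, K = 3, targets = as.Date("2012-02-29"),
                      smoothing_window = 5, smoothing_polyorder = 2)
  expect_length(ws$windows, 1)
  expect_equal(ws$windows[[1]]$donor_date, as.Date("2011-02-28"))
})

test_that("window contents match an explicit index-slicing oracle", {
  sim <- clean_sim(n_years = 3, seed = 14)
  s <- sim$series
  K <- 5; sw <- 5; sp <- 2
  td <- as.Date("2013-07-10")
  ws <- build_windows(s, K = K, targets = td,
                      smoothing_window = sw, smoothing_polyorder = sp)
  w <- ws$windows[[1]]
  scale <- max(s$values)
  # oracle: slice the matrix by explicit row arithmetic
  for (j in seq_len(K)) {
    d <- td - 1 - K + j
    i <- which(s$dates == d)
    prof <- pmin(pmax(signal::sgolayfilt(s$values[i, ], p = sp, n = sw), 0) /
                   scale, 1)
    rows <- (j - 1) * s$grid$n_slots + seq_len(s$grid$n_slots)
    expect_equal(unname(w$A[rows, "uv"]), prof)
    cd <- circular_date(as.integer(format(d, "%j")))
    expect_equal(unname(w$A[rows[1], c("doy_sin", "doy_cos")]), unname(cd))
  }
  donor_i <- which(s$dates == as.Date("2012-07-10"))
  expect_equal(unname(w$B[, "uv"]),
               pmin(pmax(signal::sgolayfilt(s$values[donor_i, ], p = sp,
                                            n = sw), 0) / scale, 1))
  # target is normalized but NOT smoothed
  ti <- which(s$dates == td)
  expect_equal(unname(w$target), unname(pmin(s$values[ti, ] / scale, 1)))
})

test_that("all window features lie in [0,1] and A has K x n_slots rows", {
  sim <- clean_sim(n_years = 2, seed = 15)
  ws <- build_windows(sim$series, K = 4, smoothing_window = 5,
                      smoothing_polyorder = 2)
  for (w in ws$windows[seq(1, length(ws$windows), by = 30)]) {
    expect_equal(nrow(w$A), 4 * sim$series$grid$n_slots)
    expect_true(all(w$A[, "uv"] >= 0 & w$A[, "uv"] <= 1))
    expect_true(all(w$B[, "uv"] >= 0 & w$B[, "uv"] <= 1))
    expect_true(all(w$target >= 0 & w$target <= 1))
  }
})

test_that("dates lacking history are skipped with a reason", {
  sim <- clean_sim(n_years = 2, seed = 16)
  s <- sim$series
  ws <- build_windows(s, K = 7,
                      targets = c(as.Date("2011-01-04"),   # no history
                                  as.Date("2012-06-01")),  # fine
                      smoothing_window = 5, smoothing_polyorder = 2)
  expect_length(ws$windows, 1)
  expect_equal(nrow(ws$skipped), 1)
  expect_match(ws$skipped$reason, "history|donor")
})
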