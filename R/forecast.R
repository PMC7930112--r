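new_uv_forecast <- function(values, dates, grid, provenance, scale,
                            horizon = rep(1L, length(dates))) {
  dimnames(values) <- list(as.character(dates), slot_labels(grid))
  structure(list(values = values, dates = as.Date(dates), grid = grid,
                 horizon = horizon, provenance = provenance, scale = scale),
            class = "uv_forecast")
}

#' @export
print.uv_forecast <- function(x, ...) {
  cat(sprintf("<uv_forecast> %d day(s), %s-%s (horizon %s)\n",
              length(x$dates), format(min(x$dates)), format(max(x$dates)),
              paste(range(x$horizon), collapse = "-")))
  invisible(x)
}

# Replace or insert one day's profile in a series.
series_upsert <- function(series, date, values) {
  i <- day_index(series, date)
  if (!is.na(i)) {
    v <- series$values; v[i, ] <- values
    imp <- series$imputed; imp[i, ] <- FALSE
    return(uv_series(v, series$dates, series$grid, imputed = imp,
                     label = series$label))
  }
  uv_series(rbind(series$values, values), c(series$dates, as.Date(date)),
            series$grid, imputed = rbind(series$imputed, FALSE),
            label = series$label)
}

#' Next-day forecast
#'
#' Assembles the model input window for each target date from observed
#' history, runs the encoder-decoder in inference mode (dropout off, so
#' repeated calls are identical) and denormalizes the output to mW/m2.
#'
#' @param model A fitted [uvnet()].
#' @param series Observed [uv_series()] providing the history.
#' @param dates Target date(s) to forecast.
#' @param covariates Optional covariates (must match the channels the
#'   model was trained with).
#' @return A `uv_forecast`: `values` (days x slots, mW/m2), `dates`,
#'   `provenance` (per date, the input days and whether each was an
#'   observation or a prior forecast), `scale`.
#' @export
forecast_next_day <- function(model, series, dates, covariates = NULL) {
  ws <- build_windows(series, K = model$K, targets = as.Date(dates),
                      lead = model$lead, scale = model$scale,
                      covariates = covariates, cov_scales = model$cov_scales,
                      smoothing_window = model$control$smoothing_window,
                      smoothing_polyorder = model$control$smoothing_polyorder,
                      with_target = FALSE)
  if (nrow(ws$skipped)) {
    stop(sprintf("cannot forecast %s: %s", format(ws$skipped$date[1]),
                 ws$skipped$reason[1]))
  }
  stacked <- stack_windows(ws)
  yhat <- nnet_forward(model$params, stacked, model$control)$Yhat
  prov <- lapply(ws$windows, function(w) {
    data.frame(day = w$input_days, source = "observed",
               stringsAsFactors = FALSE)
  })
  new_uv_forecast(yhat * model$scale,
                  vapply(ws$windows, function(w) as.character(w$date),
                         character(1)),
                  model$grid, prov, model$scale)
}

#' Autoregressive long-horizon forecast
#'
#' Forecasts days `start_date + 1 .. start_date + horizon` one day at a
#' time, feeding each day's forecast back into the input window for the
#' next step (previous-year decoder inputs always come from real data).
#' Provenance records, per step, which input days were observations and
#' which were prior forecasts.
#'
#' @param model A fitted [uvnet()].
#' @param series Observed [uv_series()] up to `start_date`.
#' @param start_date Last observed day; the first forecast day is
#'   `start_date + 1`.
#' @param horizon Number of days to forecast (>= 1).
#' @param covariates Optional covariates.
#' @return A `uv_forecast` with one row per forecast day and `horizon`
#'   recording each day's step index.
#' @export
forecast_autoregressive <- function(model, series, start_date, horizon,
                                    covariates = NULL) {
  if (horizon < 1) stop("'horizon' must be at least 1")
  start_date <- as.Date(start_date)
  working <- series
  vals <- matrix(0, horizon, model$grid$n_slots)
  dts <- start_date + seq_len(horizon)
  prov <- vector("list", horizon)
  for (h in seq_len(horizon)) {
    fc <- forecast_next_day(model, working, dts[h], covariates)
    vals[h, ] <- fc$values[1, ]
    src <- ifelse(fc$provenance[[1]]$day > start_date, "forecast", "observed")
    prov[[h]] <- data.frame(day = fc$provenance[[1]]$day, source = src,
                            stringsAsFactors = FALSE)
    working <- series_upsert(working, dts[h], vals[h, ])
  }
  new_uv_forecast(vals, dts, model$grid, prov, model$scale,
                  horizon = seq_len(horizon))
}

#' Previous-day persistence baseline
#'
#' Predicts each target day's profile to equal the previous day's
#' observed profile — the naive baseline any forecaster must beat.
#'
#' @param series Observed [uv_series()].
#' @param dates Target date(s); each previous day must be fully observed.
#' @return A `uv_forecast`.
#' @export
baseline_previous_day <- function(series, dates) {
  dates <- as.Date(dates)
  vals <- matrix(0, length(dates), series$grid$n_slots)
  prov <- vector("list", length(dates))
  for (i in seq_along(dates)) {
    prev <- dates[i] - 1
    if (!day_complete(series, prev)) {
      stop(sprintf("previous day %s is missing or incomplete", format(prev)))
    }
    vals[i, ] <- series$values[day_index(series, prev), ]
    prov[[i]] <- data.frame(day = prev, source = "observed",
                            stringsAsFactors = FALSE)
  }
  new_uv_forecast(vals, dates, series$grid, prov,
                  scale = max(series$values, na.rm = TRUE))
}

#' Forecast with a fitted model
#'
#' `horizon = 1` forecasts each of `dates`; `horizon > 1` runs the
#' autoregressive scheme from the single start date in `dates` (defaults
#' to the last day of `newdata`).
#'
#' @param object A fitted [uvnet()].
#' @param newdata Observed [uv_series()] history.
#' @param dates Target dates (`horizon = 1`) or the start date
#'   (`horizon > 1`).
#' @param horizon Forecast horizon in days.
#' @param covariates Optional covariates.
#' @param ... Unused.
#' @return A `uv_forecast`.
#' @export
predict.uvnet <- function(object, newdata, dates = NULL, horizon = 1,
                          covariates = NULL, ...) {
  if (horizon == 1) {
    if (is.null(dates)) dates <- max(newdata$dates) + 1
    forecast_next_day(object, newdata, dates, covariates)
  } else {
    if (is.null(dates)) dates <- max(newdata$dates)
    if (length(dates) != 1) {
      stop("autoregressive forecasting needs a single start date")
    }
    forecast_autoregressive(object, newdata, dates, horizon, covariates)
  }
}

# Convert a forecast to a uv_series (e.g. for write_series_csv()).
forecast_as_series <- function(fc) {
  uv_series(fc$values, fc$dates, fc$grid, label = "forecast")
}
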