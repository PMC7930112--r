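#' MAPE forecast evaluation
#'
#' Mean absolute percentage error, `100 * mean(|yhat - y| / y)`, pooled
#' over every (day, slot) term inside the daylight evaluation window
#' (default 08:00-16:00 inclusive, 49 slots on the default grid, where
#' true irradiance is bounded away from zero).  Slots whose true value
#' falls below `floor` (mW/m2) are excluded from the mean and counted in
#' the report.  The report also breaks MAPE down by hour of day and,
#' when a daily cloud-coverage covariate is supplied, by cloud-coverage
#' bin (width 0.1) together with the Spearman rank correlation between
#' per-day MAPE and coverage.
#'
#' @param forecast A `uv_forecast` (see [forecast_next_day()]) or a
#'   [uv_series()] of predictions.
#' @param truth Observed [uv_series()]; every forecast date must be
#'   present.
#' @param window Evaluation window, `c(from, to)` `"HH:MM"`, inclusive.
#' @param floor Exclude terms with true value below this (mW/m2).
#' @param cloud Optional daily [uv_covariate()] of cloud coverage in
#'   \[0, 1\].
#' @param per_day Average per day first, then across days, instead of
#'   pooling all terms.
#' @return A list of class `uv_eval`: `mape_overall`, `mape_by_hour`,
#'   `mape_by_cloud_bin`, `spearman_cloud`, `excluded_slots`, `n_days`,
#'   `per_day` (data frame of per-day MAPE).
#' @export
uv_mape <- function(forecast, truth, window = c("08:00", "16:00"),
                    floor = 1, cloud = NULL, per_day = FALSE) {
  pred_vals <- forecast$values
  pred_dates <- forecast$dates
  di <- match(pred_dates, truth$dates)
  if (anyNA(di)) {
    stop(sprintf("forecast date %s is not in the truth series",
                 format(pred_dates[which(is.na(di))[1]])))
  }
  slots <- slot_range(truth$grid, window[1], window[2])
  y <- truth$values[di, slots, drop = FALSE]
  p <- pred_vals[, slots, drop = FALSE]
  valid <- !is.na(y) & y >= floor
  if (!any(valid)) stop("no valid (day, slot) terms in the evaluation window")
  ape <- abs(p - y) / y
  ape[!valid] <- NA_real_

  per_day_mape <- 100 * rowMeans(ape, na.rm = TRUE)
  overall <- if (per_day) mean(per_day_mape)
             else 100 * mean(ape[valid])

  hour_key <- fmt_hhmm((truth$grid$slot_min[slots] %/% 60L) * 60L)
  by_hour <- vapply(split(seq_along(slots), hour_key), function(cols) {
    v <- ape[, cols]
    100 * mean(v[!is.na(v)])
  }, numeric(1))

  by_cloud <- NULL
  spearman <- NA_real_
  if (!is.null(cloud)) {
    cc <- cloud$value[match(pred_dates, cloud$date)]
    bins <- cut(cc, breaks = seq(0, 1, by = 0.1), include.lowest = TRUE,
                right = FALSE)
    ok <- !is.na(cc)
    by_cloud <- vapply(split(per_day_mape[ok], bins[ok], drop = TRUE),
                       mean, numeric(1))
    if (sum(ok) >= 3) {
      spearman <- stats::cor(cc[ok], per_day_mape[ok], method = "spearman")
    }
  }

  structure(
    list(mape_overall = overall, mape_by_hour = by_hour,
         mape_by_cloud_bin = by_cloud, spearman_cloud = spearman,
         excluded_slots = sum(!valid), n_days = length(pred_dates),
         n_terms = sum(valid), window = window, floor = floor,
         per_day = data.frame(date = pred_dates, mape = per_day_mape)),
    class = "uv_eval"
  )
}

#' @export
print.uv_eval <- function(x, ...) {
  cat(sprintf("<uv_eval> MAPE %.2f%% over %d day(s), %d terms (%s-%s, %d excluded)\n",
              x$mape_overall, x$n_days, x$n_terms, x$window[1], x$window[2],
              x$excluded_slots))
  cat("  by hour:", paste(sprintf("%s %.1f", names(x$mape_by_hour),
                                  x$mape_by_hour), collapse = ", "), "\n")
  if (!is.null(x$mape_by_cloud_bin)) {
    cat(sprintf("  Spearman(per-day MAPE, cloud) = %.3f\n", x$spearman_cloud))
  }
  invisible(x)
}
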