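#' Seasonal calendar-window imputation
#'
#' Fills each missing cell with the mean of all originally observed values
#' in the union of three donor pools: the same day's slots within
#' `slot_window` steps, the same slot on days within `day_window` calendar
#' days, and the same slot on the same month-day in years within
#' `year_window` (Feb 29 donors fall back to Feb 28).  This exploits the
#' strong diurnal and annual regularity of surface UV, so that multi-day
#' sensor outages can be bridged from neighbouring days and years.
#'
#' Donor pools use calendar arithmetic, so excluded or absent years leave
#' gaps rather than shifting donors.  Previously imputed cells are never
#' donors and are always recomputed from scratch, which makes the
#' operation idempotent and leaves observed values untouched.  Cells with
#' an empty donor pool remain missing.
#'
#' @param series A [uv_series()].
#' @param slot_window,day_window,year_window Non-negative window
#'   half-widths (defaults 2 slots, 5 days, 2 years).
#' @return A [uv_series()] with imputable cells filled and flagged in
#'   `$imputed`.
#' @export
uv_impute <- function(series, slot_window = 2, day_window = 5,
                      year_window = 2) {
  if (slot_window < 0 || day_window < 0 || year_window < 0) {
    stop("imputation windows must be non-negative")
  }
  if (slot_window + day_window + year_window == 0) {
    stop("at least one imputation window must be positive")
  }
  vals <- series$values
  donor_ok <- series$observed & !series$imputed   # originally observed only
  donor_vals <- vals
  donor_vals[!donor_ok] <- NA_real_
  n_slots <- ncol(vals)
  targets <- which(!donor_ok, arr.ind = TRUE)     # missing or prev. imputed
  out_vals <- vals
  out_imputed <- series$imputed
  for (k in seq_len(nrow(targets))) {
    d <- targets[k, 1]; s <- targets[k, 2]
    pool <- numeric(0)
    if (slot_window > 0) {
      ss <- setdiff(max(1, s - slot_window):min(n_slots, s + slot_window), s)
      pool <- c(pool, donor_vals[d, ss])
    }
    if (day_window > 0) {
      dd <- series$dates[d] + setdiff(-day_window:day_window, 0)
      di <- match(dd, series$dates)
      pool <- c(pool, donor_vals[cbind(di[!is.na(di)], s)])
    }
    if (year_window > 0) {
      yy <- year_of(series$dates[d]) + setdiff(-year_window:year_window, 0)
      dd <- vapply(yy, function(y) same_date_in_year(series$dates[d], y),
                   as.Date(NA))
      di <- match(as.Date(dd, origin = "1970-01-01"), series$dates)
      pool <- c(pool, donor_vals[cbind(di[!is.na(di)], s)])
    }
    pool <- pool[!is.na(pool)]
    if (length(pool)) {
      out_vals[d, s] <- mean(pool)
      out_imputed[d, s] <- TRUE
    } else {
      out_vals[d, s] <- NA_real_
      out_imputed[d, s] <- FALSE
    }
  }
  uv_series(out_vals, series$dates, series$grid, imputed = out_imputed,
            label = series$label)
}
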