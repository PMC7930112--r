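#' Weighted irradiance series
#'
#' The central data container: a day-by-slot matrix of action-spectrum
#' weighted irradiance (mW/m2) on a fixed daily grid, with an observation
#' mask.  Missing cells are `NA` in `values` and `FALSE` in `observed`.
#' Cells filled by [uv_impute()] carry a value, are `TRUE` in `observed`,
#' and are additionally flagged in `imputed` so that re-imputation never
#' treats them as donors.
#'
#' @param values Numeric matrix, days in rows and grid slots in columns.
#'   `NA` marks missing observations.
#' @param dates `Date` vector, one per row, strictly increasing.
#' @param grid A [uv_grid()]; `ncol(values)` must equal `grid$n_slots`.
#' @param imputed Optional logical matrix flagging imputed cells.
#' @param label Free-text label (e.g. `"antipsoriatic"`).
#' @return An object of class `uv_series` with elements `values`, `dates`,
#'   `grid`, `observed`, `imputed` and `label`.
#' @export
uv_series <- function(values, dates, grid = uv_grid(), imputed = NULL,
                      label = "") {
  values <- as.matrix(values)
  dates <- as.Date(dates)
  if (nrow(values) != length(dates)) {
    stop("number of rows of 'values' must match length of 'dates'")
  }
  if (ncol(values) != grid$n_slots) {
    stop(sprintf("'values' has %d columns but the grid has %d slots",
                 ncol(values), grid$n_slots))
  }
  if (anyDuplicated(dates)) stop("duplicate dates in series")
  if (is.unsorted(dates, strictly = TRUE)) {
    ord <- order(dates)
    values <- values[ord, , drop = FALSE]
    dates <- dates[ord]
    if (!is.null(imputed)) imputed <- imputed[ord, , drop = FALSE]
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("irradiance values must be non-negative")
  }
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values))
  }
  dimnames(values) <- list(as.character(dates), slot_labels(grid))
  dimnames(imputed) <- dimnames(values)
  structure(
    list(values = values, dates = dates, grid = grid,
         observed = !is.na(values), imputed = imputed, label = label),
    class = "uv_series"
  )
}

#' @export
print.uv_series <- function(x, ...) {
  n_miss <- sum(!x$observed)
  cat(sprintf("<uv_series>%s %d day(s) x %d slots, %s-%s",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$values), ncol(x$values),
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("\n  missing cells: %d, imputed cells: %d\n",
              n_miss, sum(x$imputed)))
  invisible(x)
}

#' @export
dim.uv_series <- function(x) dim(x$values)

#' Extract days from a series
#'
#' @param x A `uv_series`.
#' @param i Row (day) selector: indices, logical, or `Date`s.
#' @param ... Unused.
#' @return A `uv_series` restricted to the selected days.
#' @export
`[.uv_series` <- function(x, i, ...) {
  if (inherits(i, "Date") || is.character(i)) {
    i <- match(as.Date(i), x$dates)
    if (anyNA(i)) stop("some requested dates are not in the series")
  }
  uv_series(x$values[i, , drop = FALSE], x$dates[i], x$grid,
            imputed = x$imputed[i, , drop = FALSE], label = x$label)
}

# Row index of a date; NA when absent.
day_index <- function(series, date) match(as.Date(date), series$dates)

# TRUE when the day is present with no missing slot.
day_complete <- function(series, date) {
  i <- day_index(series, date)
  !is.na(i) && all(series$observed[i, ])
}

# Bind two series on the same grid (dates must not overlap).
rbind_series <- function(a, b) {
  stopifnot(identical(a$grid$slot_min, b$grid$slot_min))
  uv_series(rbind(a$values, b$values), c(a$dates, b$dates), a$grid,
            imputed = rbind(a$imputed, b$imputed), label = a$label)
}

#' Complete a series to a contiguous calendar
#'
#' Inserts fully-missing rows for any calendar dates absent between the
#' first and last day of the series (sensor outages appear as absent rows
#' in long-format files; imputation needs them present as missing days).
#'
#' @param series A [uv_series()].
#' @return A `uv_series` covering every date in the range.
#' @export
complete_calendar <- function(series) {
  full <- seq(min(series$dates), max(series$dates), by = "day")
  if (length(full) == length(series$dates)) return(series)
  vals <- matrix(NA_real_, length(full), ncol(series$values))
  imp <- matrix(FALSE, length(full), ncol(series$values))
  idx <- match(series$dates, full)
  vals[idx, ] <- series$values
  imp[idx, ] <- series$imputed
  uv_series(vals, full, series$grid, imputed = imp, label = series$label)
}

#' Restrict a series to calendar years
#'
#' @param series A [uv_series()].
#' @param years Integer vector of calendar years to keep.
#' @return A `uv_series` with only the matching days.
#' @export
series_years <- function(series, years) {
  keep <- year_of(series$dates) %in% years
  if (!any(keep)) stop("no days in the requested years")
  series[which(keep)]
}

year_of <- function(d) as.integer(format(d, "%Y"))
month_day <- function(d) format(d, "%m-%d")

# Same month-day in another year; Feb 29 falls back to Feb 28.
same_date_in_year <- function(date, year) {
  md <- month_day(date)
  if (md == "02-29") md <- "02-28"
  as.Date(sprintf("%04d-%s", year, md))
}
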