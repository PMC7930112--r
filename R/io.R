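# CSV contracts (all comma-separated, header mandatory, ISO-8601 local
# timestamps without timezone suffix; timestamps label slot starts):
#   spectral.csv : datetime,wavelength_nm,irradiance_mw_m2_nm
#   series.csv   : datetime,value_mw_m2
#   covariate.csv: datetime,name,value       (daily rows may omit the time)
#   action_spectrum.csv: wavelength_nm,weight

# Parse "YYYY-MM-DD[ T]HH:MM[:SS]" into (date, minute-of-day). Timezone
# suffixes are deliberately rejected: instrument local time is the frame.
parse_datetime <- function(x) {
  m <- regmatches(x, regexec(
    "^([0-9]{4}-[0-9]{2}-[0-9]{2})[ T]([0-9]{2}):([0-9]{2})(:[0-9]{2})?$", x))
  bad <- vapply(m, length, integer(1)) != 5L
  list(date = as.Date(vapply(m, function(p) if (length(p) == 5L) p[2] else NA_character_,
                             character(1))),
       minute = ifelse(bad, NA_integer_,
                       vapply(m, function(p) {
                         if (length(p) != 5L) return(NA_integer_)
                         as.integer(p[3]) * 60L + as.integer(p[4])
                       }, integer(1))),
       bad = bad)
}

fmt_datetime <- function(date, minute) {
  sprintf("%s %s:00", format(date), fmt_hhmm(minute))
}

# Deterministic numeric formatting used by all writers (round-trip safe to
# 15 significant digits).
fmt_num <- function(x) sprintf("%.15g", x)

read_contract_csv <- function(path, columns) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")))
  }
  df
}

check_on_grid <- function(dt, grid, path) {
  if (any(dt$bad)) {
    stop(sprintf("%s: malformed datetime at data line %d ('%s')",
                 path, which(dt$bad)[1], NA))
  }
  idx <- slot_index(grid, dt$minute)
  if (anyNA(idx)) {
    i <- which(is.na(idx))[1]
    stop(sprintf("%s: timestamp %s %s does not fall on the measurement grid",
                 path, format(dt$date[i]), fmt_hhmm(dt$minute[i])))
  }
  idx
}

#' Read spectral irradiance scans
#'
#' Reads a long-format CSV of 1-nm resolution spectral scans (columns
#' `datetime,wavelength_nm,irradiance_mw_m2_nm`) into one spectral day per
#' calendar date.  Grid slots with no rows are flagged missing.
#'
#' @param path CSV file path.
#' @param grid A [uv_grid()].
#' @param wavelengths Admissible wavelength range in nm; rows outside it
#'   are an error.
#' @return A list of `uv_spectral_day` objects (one per date, in date
#'   order), each with elements `date`, `wavelengths`, `spectra`
#'   (slot-by-wavelength matrix, mW/m2/nm, `NA` rows where the slot was
#'   not scanned), `observed` (per-slot flag) and `grid`.
#' @export
read_spectral_csv <- function(path, grid = uv_grid(),
                              wavelengths = c(280, 400)) {
  df <- read_contract_csv(path, c("datetime", "wavelength_nm",
                                  "irradiance_mw_m2_nm"))
  wl <- suppressWarnings(as.numeric(df$wavelength_nm))
  ir <- suppressWarnings(as.numeric(df$irradiance_mw_m2_nm))
  if (anyNA(wl) || anyNA(ir)) {
    i <- which(is.na(wl) | is.na(ir))[1]
    stop(sprintf("%s: malformed numeric value at data line %d", path, i))
  }
  out_of_band <- wl < wavelengths[1] | wl > wavelengths[2]
  if (any(out_of_band)) {
    i <- which(out_of_band)[1]
    stop(sprintf("%s: wavelength %g nm at data line %d outside [%g, %g]",
                 path, wl[i], i, wavelengths[1], wavelengths[2]))
  }
  if (any(ir < 0)) {
    i <- which(ir < 0)[1]
    stop(sprintf("%s: negative irradiance at data line %d", path, i))
  }
  dt <- parse_datetime(df$datetime)
  if (any(dt$bad)) {
    stop(sprintf("%s: malformed datetime at data line %d ('%s')",
                 path, which(dt$bad)[1], df$datetime[which(dt$bad)[1]]))
  }
  slot <- check_on_grid(dt, grid, path)

  wls <- sort(unique(wl))
  dates <- sort(unique(dt$date))
  lapply(dates, function(d) {
    rows <- which(dt$date == d)
    spectra <- matrix(NA_real_, grid$n_slots, length(wls),
                      dimnames = list(slot_labels(grid), wls))
    key_seen <- paste(slot[rows], match(wl[rows], wls))
    if (anyDuplicated(key_seen)) {
      stop(sprintf("%s: duplicate (timestamp, wavelength) row on %s",
                   path, format(d)))
    }
    spectra[cbind(slot[rows], match(wl[rows], wls))] <- ir[rows]
    observed <- rowSums(!is.na(spectra)) > 0
    # A scanned slot must carry the full wavelength vector.
    partial <- observed & rowSums(is.na(spectra)) > 0
    if (any(partial)) {
      stop(sprintf("%s: slot %s on %s has a partial spectrum",
                   path, slot_labels(grid)[which(partial)[1]], format(d)))
    }
    structure(list(date = d, wavelengths = wls, spectra = spectra,
                   observed = observed, grid = grid),
              class = "uv_spectral_day")
  })
}

#' @export
print.uv_spectral_day <- function(x, ...) {
  cat(sprintf("<uv_spectral_day> %s: %d slots (%d scanned), %d wavelengths (%g-%g nm)\n",
              format(x$date), length(x$observed), sum(x$observed),
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Read a weighted irradiance series
#'
#' Reads a long-format CSV (columns `datetime,value_mw_m2`) into a
#' [uv_series()].  Cells absent from the file are flagged missing.
#'
#' @param path CSV file path.
#' @param grid A [uv_grid()].
#' @param label Label attached to the returned series.
#' @return A [uv_series()].
#' @export
read_series_csv <- function(path, grid = uv_grid(), label = "") {
  df <- read_contract_csv(path, c("datetime", "value_mw_m2"))
  val <- suppressWarnings(as.numeric(df$value_mw_m2))
  if (anyNA(val)) {
    stop(sprintf("%s: malformed numeric value at data line %d",
                 path, which(is.na(val))[1]))
  }
  if (any(val < 0)) {
    stop(sprintf("%s: negative irradiance at data line %d",
                 path, which(val < 0)[1]))
  }
  dt <- parse_datetime(df$datetime)
  if (any(dt$bad)) {
    stop(sprintf("%s: malformed datetime at data line %d ('%s')",
                 path, which(dt$bad)[1], df$datetime[which(dt$bad)[1]]))
  }
  if (anyDuplicated(df$datetime)) {
    stop(sprintf("%s: duplicate timestamp '%s'",
                 path, df$datetime[anyDuplicated(df$datetime)]))
  }
  slot <- check_on_grid(dt, grid, path)
  dates <- sort(unique(dt$date))
  values <- matrix(NA_real_, length(dates), grid$n_slots)
  values[cbind(match(dt$date, dates), slot)] <- val
  uv_series(values, dates, grid, label = label)
}

#' Write a weighted irradiance series
#'
#' Long-format CSV, chronological row order, missing cells omitted.
#' Output is byte-deterministic for identical input.
#'
#' @param series A [uv_series()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_series_csv <- function(series, path) {
  lines <- "datetime,value_mw_m2"
  for (i in seq_along(series$dates)) {
    obs <- which(series$observed[i, ])
    if (!length(obs)) next
    lines <- c(lines, sprintf("%s,%s",
                              fmt_datetime(series$dates[i],
                                           series$grid$slot_min[obs]),
                              fmt_num(series$values[i, obs])))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Exogenous covariate series
#'
#' A named covariate (total ozone column in DU, AOD500, cloud coverage,
#' ...) at per-slot, hourly or daily native resolution.
#'
#' @param name Covariate name.
#' @param date `Date` vector, one per observation.
#' @param minute Minute-of-day per observation; `NA` for daily values.
#' @param value Numeric values.
#' @param resolution `"slot"`, `"hourly"` or `"daily"`; inferred from the
#'   timestamps when `NULL`.
#' @return An object of class `uv_covariate`.
#' @export
uv_covariate <- function(name, date, minute, value, resolution = NULL) {
  date <- as.Date(date)
  stamp <- paste(date, minute)
  if (anyDuplicated(stamp)) stop("duplicate covariate timestamps")
  ord <- order(date, minute, na.last = FALSE)
  date <- date[ord]; minute <- minute[ord]; value <- value[ord]
  if (is.null(resolution)) {
    resolution <- if (all(is.na(minute))) "daily"
                  else if (all(minute %% 60L == 0L, na.rm = TRUE)) "hourly"
                  else "slot"
  }
  resolution <- match.arg(resolution, c("slot", "hourly", "daily"))
  structure(list(name = name, date = date, minute = minute, value = value,
                 resolution = resolution),
            class = "uv_covariate")
}

#' @export
print.uv_covariate <- function(x, ...) {
  cat(sprintf("<uv_covariate> %s (%s resolution), %d observations, %s-%s\n",
              x$name, x$resolution, length(x$value),
              format(min(x$date)), format(max(x$date))))
  invisible(x)
}

#' Read covariate series
#'
#' Columns `datetime,name,value`; daily values may use a bare date.
#' Returns one [uv_covariate()] per distinct `name`.
#'
#' @param path CSV file path.
#' @return Named list of [uv_covariate()] objects.
#' @export
read_covariate_csv <- function(path) {
  df <- read_contract_csv(path, c("datetime", "name", "value"))
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    stop(sprintf("%s: malformed numeric value at data line %d",
                 path, which(is.na(val))[1]))
  }
  is_daily <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", df$datetime)
  dt <- parse_datetime(ifelse(is_daily, paste(df$datetime, "00:00"),
                              df$datetime))
  if (any(dt$bad)) {
    stop(sprintf("%s: malformed datetime at data line %d ('%s')",
                 path, which(dt$bad)[1], df$datetime[which(dt$bad)[1]]))
  }
  minute <- ifelse(is_daily, NA_integer_, dt$minute)
  out <- lapply(split(seq_len(nrow(df)), df$name), function(rows) {
    uv_covariate(df$name[rows[1]], dt$date[rows], minute[rows], val[rows])
  })
  out[order(names(out))]
}

#' Write covariate series
#'
#' @param covs List of [uv_covariate()] objects (or a single one).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_covariate_csv <- function(covs, path) {
  if (inherits(covs, "uv_covariate")) covs <- list(covs)
  lines <- "datetime,name,value"
  for (cv in covs) {
    stamp <- ifelse(is.na(cv$minute), format(cv$date),
                    fmt_datetime(cv$date, ifelse(is.na(cv$minute), 0L,
                                                 cv$minute)))
    lines <- c(lines, sprintf("%s,%s,%s", stamp, cv$name, fmt_num(cv$value)))
  }
  writeLines(lines, path)
  invisible(path)
}
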