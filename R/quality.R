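#' Day-profile quality filter
#'
#' Flags whole days whose irradiance profile is anomalous and should not
#' enter model evaluation: highly skewed profiles (|sample skewness| above
#' `max_abs_skewness`), disproportional profiles (max/min ratio above
#' `max_ratio`), and profiles whose maximum falls outside
#' \[`floor`, `ceiling`\] mW/m2.  Statistics are computed over the daylight
#' window (default 08:00-16:00, 49 slots on the default grid), where
#' irradiance is bounded away from the dawn/dusk zeros that would make the
#' min (and hence the ratio) degenerate.
#'
#' Skewness is the adjusted Fisher-Pearson sample skewness
#' (`e1071::skewness(type = 2)`).  Days containing missing cells inside
#' the window cannot be assessed and are rejected with rule `"missing"`;
#' run [uv_impute()] first.  A day whose window minimum is 0 fails the
#' ratio rule (division guard).
#'
#' @param series A [uv_series()].
#' @param max_abs_skewness,max_ratio,ceiling,floor Thresholds (defaults
#'   0.3, 15, 400 mW/m2, 150 mW/m2).
#' @param window Daylight evaluation window, `c(from, to)` `"HH:MM"`
#'   strings, inclusive.
#' @return A list of class `uv_quality` with `series` (days retained),
#'   `rejected` (data frame `date`, `rules` with comma-joined rule names
#'   among `skewness`, `ratio`, `ceiling`, `floor`, `missing`) and the
#'   thresholds used.
#' @export
uv_quality_filter <- function(series, max_abs_skewness = 0.3, max_ratio = 15,
                              ceiling = 400, floor = 150,
                              window = c("08:00", "16:00")) {
  if (ceiling <= floor || floor <= 0) stop("need ceiling > floor > 0")
  if (max_ratio <= 1) stop("'max_ratio' must exceed 1")
  if (max_abs_skewness <= 0) stop("'max_abs_skewness' must be positive")
  slots <- slot_range(series$grid, window[1], window[2])
  rules <- lapply(seq_along(series$dates), function(i) {
    x <- series$values[i, slots]
    if (anyNA(x)) return("missing")
    r <- character(0)
    if (abs(e1071::skewness(x, type = 2)) > max_abs_skewness) {
      r <- c(r, "skewness")
    }
    if (min(x) <= 0 || max(x) / min(x) > max_ratio) r <- c(r, "ratio")
    if (max(x) > ceiling) r <- c(r, "ceiling")
    if (max(x) < floor) r <- c(r, "floor")
    r
  })
  bad <- vapply(rules, length, integer(1)) > 0
  rejected <- data.frame(
    date = series$dates[bad],
    rules = vapply(rules[bad], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  kept <- series[which(!bad)]
  structure(list(series = kept, rejected = rejected,
                 thresholds = list(max_abs_skewness = max_abs_skewness,
                                   max_ratio = max_ratio, ceiling = ceiling,
                                   floor = floor, window = window)),
            class = "uv_quality")
}

#' @export
print.uv_quality <- function(x, ...) {
  cat(sprintf("<uv_quality> kept %d day(s), rejected %d\n",
              nrow(x$series$values), nrow(x$rejected)))
  if (nrow(x$rejected)) print(x$rejected, row.names = FALSE)
  invisible(x)
}
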