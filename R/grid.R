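#' Daily measurement grid
#'
#' Defines the fixed within-day sampling grid of a UV monitoring station:
#' scans every `step` minutes from `start` to `end` inclusive.  The default
#' grid (05:00 to 19:00 every 10 min) has 85 slots, matching a
#' double-monochromator station scanning from 5 AM to 7 PM local time.
#'
#' @param start,end Time of day as `"HH:MM"` strings.  Both endpoints are
#'   slots (the grid is closed on both ends).
#' @param step Slot spacing in minutes; must divide the span exactly.
#' @return An object of class `uv_grid` with elements `start_min`,
#'   `end_min`, `step`, `n_slots` and `slot_min` (minutes since midnight
#'   for every slot).
#' @examples
#' g <- uv_grid()
#' g$n_slots  # 85
#' @export
uv_grid <- function(start = "05:00", end = "19:00", step = 10) {
  start_min <- parse_hhmm(start)
  end_min <- parse_hhmm(end)
  if (end_min <= start_min) stop("grid end must be after start")
  step <- as.integer(step)
  if (step <= 0L) stop("grid step must be positive")
  span <- end_min - start_min
  if (span %% step != 0L) {
    stop(sprintf("grid step (%d min) must divide the span (%d min) exactly",
                 step, span))
  }
  slot_min <- seq(start_min, end_min, by = step)
  structure(
    list(start_min = start_min, end_min = end_min, step = step,
         n_slots = length(slot_min), slot_min = slot_min),
    class = "uv_grid"
  )
}

#' @export
print.uv_grid <- function(x, ...) {
  cat(sprintf("<uv_grid> %s-%s every %d min (%d slots)\n",
              fmt_hhmm(x$start_min), fmt_hhmm(x$end_min), x$step, x$n_slots))
  invisible(x)
}

parse_hhmm <- function(x) {
  if (inherits(x, "difftime")) x <- format(x)
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) stop(sprintf("cannot parse time of day '%s'", x))
  as.integer(m[2]) * 60L + as.integer(m[3])
}

fmt_hhmm <- function(min) sprintf("%02d:%02d", min %/% 60L, min %% 60L)

#' Labels for the slots of a grid
#'
#' @param grid A [uv_grid()].
#' @return Character vector of `"HH:MM"` labels, one per slot.
#' @export
slot_labels <- function(grid) vapply(grid$slot_min, fmt_hhmm, character(1))

# Indices of slots whose time lies in [from, to] (HH:MM strings, inclusive).
slot_range <- function(grid, from, to) {
  which(grid$slot_min >= parse_hhmm(from) & grid$slot_min <= parse_hhmm(to))
}

# Map minutes-since-midnight to slot index; NA when off-grid.
slot_index <- function(grid, minutes) {
  idx <- match(minutes, grid$slot_min)
  idx
}
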