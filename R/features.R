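#' Circular day-of-year encoding
#'
#' Encodes the day of year on the unit circle so the model can learn the
#' annual cycle without a discontinuity at New Year:
#' `(sin(2*pi*d/365), cos(2*pi*d/365))` with `d = day_of_year - 1`
#' (Jan 1 maps to (0, 1); any fixed origin is equivalent up to rotation).
#'
#' @param day_of_year Integer(s) in 1..366.
#' @return A length-2 vector `(sin, cos)`, or a 2-column matrix for
#'   vector input.
#' @export
circular_date <- function(day_of_year) {
  if (any(day_of_year < 1 | day_of_year > 366)) {
    stop("'day_of_year' must lie in 1..366")
  }
  d <- day_of_year - 1
  out <- cbind(sin = sin(2 * pi * d / 365), cos = cos(2 * pi * d / 365))
  if (length(day_of_year) == 1L) out[1, ] else out
}

day_of_year <- function(date) as.integer(format(as.Date(date), "%j"))

#' Savitzky-Golay input denoising
#'
#' Smooths a single day's slot profile with a Savitzky-Golay filter
#' (local least-squares polynomial fit), removing isolated noise spikes
#' while preserving the bell shape.  Applied to model *inputs* only;
#' training targets are never smoothed, so the model learns to predict
#' real (noisy) irradiance.  Negative filter outputs are clipped to 0.
#'
#' @param x Numeric slot profile.
#' @param window Odd filter length in slots (default 11); `window = 1` is
#'   the identity.
#' @param polyorder Polynomial order, `< window` (default 3).
#' @return Smoothed profile, same length as `x`.
#' @export
smooth_profile <- function(x, window = 11, polyorder = 3) {
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window > length(x)) stop("'window' must not exceed the profile length")
  if (polyorder >= window) stop("'polyorder' must be smaller than 'window'")
  if (window == 1) return(x)
  pmax(signal::sgolayfilt(x, p = polyorder, n = window), 0)
}

#' Normalize a series to \[0, 1\]
#'
#' Divides by a single global scale (mW/m2).  When `scale` is omitted it
#' is set to the maximum observed value of `series` — by convention the
#' *training* portion, so that day-to-day amplitude information is
#' preserved.  Values from other splits may exceed the training maximum
#' and are clipped to 1.
#'
#' @param series A [uv_series()].
#' @param scale Positive scale in mW/m2, or `NULL` to use the series
#'   maximum.
#' @return The normalized `uv_series`, with the scale in attribute
#'   `"scale"`.
#' @seealso [uv_denormalize()]
#' @export
uv_normalize <- function(series, scale = NULL) {
  if (is.null(scale)) scale <- max(series$values, na.rm = TRUE)
  if (!is.finite(scale) || scale <= 0) stop("'scale' must be positive")
  vals <- pmin(series$values / scale, 1)
  out <- uv_series(vals, series$dates, series$grid, imputed = series$imputed,
                   label = series$label)
  attr(out, "scale") <- scale
  out
}

#' @rdname uv_normalize
#' @export
uv_denormalize <- function(series, scale = attr(series, "scale")) {
  if (is.null(scale)) stop("no normalization scale available")
  out <- uv_series(series$values * scale, series$dates, series$grid,
                   imputed = series$imputed, label = series$label)
  attr(out, "scale") <- NULL
  out
}

#' Align a covariate to the measurement grid
#'
#' Duplicates lower-resolution covariate values to the grid's 10-min
#' resolution: hourly values repeat across the slots of their hour, daily
#' values repeat across all slots, per-slot values pass through.
#'
#' @param cov A [uv_covariate()].
#' @param grid A [uv_grid()].
#' @param dates `Date` vector of requested days.
#' @return Numeric matrix `length(dates)` x `grid$n_slots`; `NA` where no
#'   covariate value covers a slot.
#' @export
align_covariate <- function(cov, grid, dates) {
  dates <- as.Date(dates)
  out <- matrix(NA_real_, length(dates), grid$n_slots,
                dimnames = list(as.character(dates), slot_labels(grid)))
  for (i in seq_along(dates)) {
    rows <- which(cov$date == dates[i])
    if (!length(rows)) next
    out[i, ] <- switch(cov$resolution,
      daily = rep(cov$value[rows[1]], grid$n_slots),
      hourly = {
        hr <- grid$slot_min %/% 60L
        cov$value[rows][match(hr * 60L, cov$minute[rows])]
      },
      slot = cov$value[rows][match(grid$slot_min, cov$minute[rows])]
    )
  }
  out
}

# ---- model input windows -------------------------------------------------

# Smooth (inputs only), normalize and clip one day's profile.
prep_input_profile <- function(x, scale, window, polyorder) {
  pmin(smooth_profile(x, window, polyorder) / scale, 1)
}

# Previous-year donor profile for a target date: same month-day last year,
# else two years back, else the climatological per-slot mean over all
# complete same-month-day profiles from earlier years (never the future).
find_donor <- function(series, date) {
  for (back in 1:2) {
    d <- same_date_in_year(date, year_of(date) - back)
    if (day_complete(series, d)) {
      return(list(values = series$values[day_index(series, d), ],
                  date = d, source = sprintf("year-%d", back)))
    }
  }
  md <- month_day(date)
  if (md == "02-29") md <- "02-28"
  cand <- which(month_day(series$dates) == md & series$dates < as.Date(date))
  cand <- cand[apply(series$observed[cand, , drop = FALSE], 1, all)]
  if (length(cand)) {
    return(list(values = colMeans(series$values[cand, , drop = FALSE]),
                date = as.Date(NA), source = "climatology"))
  }
  NULL
}

#' Assemble model input windows
#'
#' For each target date builds the forecaster's input: `A`, the smoothed
#' and normalized profiles of the `K` days ending `lead` days before the
#' target (each slot carrying the UV value, the circular-date features of
#' its day, and any covariate channels), flattened to one contiguous
#' sequence of `K * n_slots` timesteps; `B`, the same-features profile of
#' the previous year's same month-day (the decoder input); and, when
#' available, the *unsmoothed* normalized target-day profile.  Dates
#' lacking the required complete history are skipped, not fatal.
#'
#' @param series A [uv_series()] (impute first: only complete days are
#'   usable).
#' @param K Number of past days fed to the encoder (7, 14 or 21 in the
#'   reference configuration; any positive value is accepted).
#' @param targets `Date` vector of forecast dates; defaults to every date
#'   in the series for which a target profile exists.
#' @param lead Days ahead of the last input day (1 = next-day forecast;
#'   larger values train the "forecast specific date" variant).
#' @param scale Normalization scale (mW/m2); defaults to the series
#'   maximum.  Pass the training-set scale when building validation or
#'   test windows.
#' @param covariates Optional list of [uv_covariate()]; values are aligned
#'   to the grid, divided by `cov_scales` and clipped to \[0, 1\].
#' @param cov_scales Optional named scales for the covariates; defaults to
#'   each covariate's maximum value.
#' @param smoothing_window,smoothing_polyorder Savitzky-Golay parameters
#'   for input denoising (see [smooth_profile()]).
#' @param with_target Keep target profiles (training) or omit them
#'   (forecasting).
#' @return A list of class `uv_windows`: `windows` (per-date list with
#'   `date`, `A`, `B`, `target`, `input_days`, `donor_date`,
#'   `donor_source`), `skipped` (data frame `date`, `reason`), `scale`,
#'   `cov_scales`, `feature_names`, `K`, `lead`, `grid`.
#' @export
build_windows <- function(series, K = 14, targets = NULL, lead = 1,
                          scale = NULL, covariates = NULL, cov_scales = NULL,
                          smoothing_window = 11, smoothing_polyorder = 3,
                          with_target = TRUE) {
  if (K < 1) stop("'K' must be positive")
  if (lead < 1) stop("'lead' must be positive")
  if (is.null(scale)) scale <- max(series$values, na.rm = TRUE)
  grid <- series$grid
  S <- grid$n_slots
  if (is.null(targets)) targets <- series$dates
  targets <- as.Date(targets)

  cov_names <- character(0)
  cov_mats <- list()
  if (length(covariates)) {
    cov_names <- vapply(covariates, function(cv) cv$name, character(1))
    if (is.null(cov_scales)) {
      cov_scales <- vapply(covariates, function(cv) max(abs(cv$value)),
                           numeric(1))
      names(cov_scales) <- cov_names
    }
  }
  feature_names <- c("uv", "doy_sin", "doy_cos", cov_names)

  # per-day feature block: S x n_features
  day_block <- function(date, uv_profile, smooth) {
    uv <- if (smooth) {
      prep_input_profile(uv_profile, scale, smoothing_window,
                         smoothing_polyorder)
    } else pmin(uv_profile / scale, 1)
    cd <- circular_date(day_of_year(date))
    block <- cbind(uv, doy_sin = cd[1], doy_cos = cd[2])
    for (j in seq_along(covariates)) {
      cm <- align_covariate(covariates[[j]], grid, date)[1, ]
      cm[is.na(cm)] <- 0   # absent covariate values contribute a zero channel
      block <- cbind(block, pmin(pmax(cm / cov_scales[j], 0), 1))
    }
    colnames(block) <- feature_names
    block
  }

  windows <- list()
  skipped <- list()
  for (td in as.list(targets)) {
    input_days <- td - lead - (K:1) + 1
    if (!all(vapply(input_days, day_complete, logical(1), series = series))) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(date = td, reason = "incomplete input history")
      next
    }
    donor <- find_donor(series, td)
    if (is.null(donor)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(date = td, reason = "no previous-year donor")
      next
    }
    target <- NULL
    if (with_target) {
      if (!day_complete(series, td)) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(date = td, reason = "target day incomplete")
        next
      }
      target <- pmin(series$values[day_index(series, td), ] / scale, 1)
    }
    A <- do.call(rbind, lapply(as.list(input_days), function(d) {
      day_block(d, series$values[day_index(series, d), ], smooth = TRUE)
    }))
    B <- day_block(td, donor$values, smooth = TRUE)
    windows[[length(windows) + 1L]] <- list(
      date = td, A = A, B = B, target = target,
      input_days = input_days, donor_date = donor$date,
      donor_source = donor$source
    )
  }
  structure(
    list(windows = windows,
         skipped = if (length(skipped)) do.call(rbind, skipped)
                   else data.frame(date = as.Date(character()),
                                   reason = character()),
         scale = scale, cov_scales = cov_scales,
         feature_names = feature_names, K = K, lead = lead, grid = grid),
    class = "uv_windows"
  )
}

#' @export
print.uv_windows <- function(x, ...) {
  cat(sprintf("<uv_windows> %d window(s) (K = %d, lead = %d, %d features), %d skipped\n",
              length(x$windows), x$K, x$lead, length(x$feature_names),
              nrow(x$skipped)))
  invisible(x)
}

# Stack windows for batched network passes: lists of per-timestep
# batch x features matrices plus the target matrix.
stack_windows <- function(ws) {
  windows <- ws$windows
  if (!length(windows)) stop("no windows to stack")
  nb <- length(windows)
  f <- length(ws$feature_names)
  Ta <- nrow(windows[[1]]$A)
  S <- nrow(windows[[1]]$B)
  A_arr <- vapply(windows, function(w) w$A, matrix(0, Ta, f))
  B_arr <- vapply(windows, function(w) w$B, matrix(0, S, f))
  A <- lapply(seq_len(Ta), function(t) {
    m <- matrix(A_arr[t, , ], nrow = f); t(m)
  })
  Bq <- lapply(seq_len(S), function(t) {
    m <- matrix(B_arr[t, , ], nrow = f); t(m)
  })
  Y <- NULL
  if (!is.null(windows[[1]]$target)) {
    Y <- t(vapply(windows, function(w) w$target, numeric(S)))
  }
  list(A = A, B = Bq, Y = Y, n = nb, n_slots = S, n_steps = Ta)
}
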