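#' Biological action spectrum
#'
#' Wavelength-dependent relative effectiveness used to weight a measured
#' UV spectrum into a biologically effective irradiance (e.g. psoriasis
#' clearance, erythema, vitamin D synthesis).  The weighting table is
#' pluggable: supply any published spectrum as a `(wavelength, weight)`
#' table.  [flat_spectrum()] and [delta_spectrum()] provide degenerate
#' spectra for testing.
#'
#' @param wavelengths Wavelengths in nm, sorted, within \[280, 400\].
#' @param weights Non-negative relative effectiveness per wavelength.
#' @param name Spectrum name.
#' @return An object of class `action_spectrum`.
#' @export
action_spectrum <- function(wavelengths, weights, name = "custom") {
  if (length(wavelengths) != length(weights)) {
    stop("'wavelengths' and 'weights' must have equal length")
  }
  if (is.unsorted(wavelengths, strictly = TRUE)) {
    stop("'wavelengths' must be strictly increasing")
  }
  if (any(wavelengths < 280 | wavelengths > 400)) {
    stop("action spectrum wavelengths must lie within [280, 400] nm")
  }
  if (any(weights < 0)) stop("action spectrum weights must be non-negative")
  structure(list(wavelengths = as.numeric(wavelengths),
                 weights = as.numeric(weights), name = name),
            class = "action_spectrum")
}

#' @export
print.action_spectrum <- function(x, ...) {
  cat(sprintf("<action_spectrum> %s: %d wavelengths (%g-%g nm)\n",
              x$name, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @rdname action_spectrum
#' @param value Weight given to every wavelength (flat) or to the single
#'   wavelength `at` (delta).
#' @export
flat_spectrum <- function(wavelengths = 280:400, value = 1) {
  action_spectrum(wavelengths, rep(value, length(wavelengths)), "flat")
}

#' @rdname action_spectrum
#' @param at Wavelength (nm) carrying the unit weight.
#' @export
delta_spectrum <- function(at = 311, wavelengths = 280:400, value = 1) {
  w <- ifelse(wavelengths == at, value, 0)
  if (!any(w > 0)) stop("'at' is not among 'wavelengths'")
  action_spectrum(wavelengths, w, sprintf("delta@%gnm", at))
}

#' Read an action spectrum table
#'
#' CSV with columns `wavelength_nm,weight`.
#'
#' @param path CSV file path.
#' @param name Spectrum name (defaults to the file base name).
#' @return An [action_spectrum()].
#' @export
read_action_spectrum <- function(path, name = NULL) {
  df <- read_contract_csv(path, c("wavelength_nm", "weight"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  action_spectrum(as.numeric(df$wavelength_nm), as.numeric(df$weight), name)
}

#' Weight a spectral day into effective irradiance
#'
#' Collapses each slot's spectrum into a single biologically effective
#' irradiance by the rectangle rule over 1-nm bands:
#' `sum_over_lambda( weight(lambda) * spectral(lambda) * 1 nm )`, in mW/m2.
#' Masked slots stay masked.
#'
#' @param day A `uv_spectral_day` (see [read_spectral_csv()]) or a list of
#'   them.
#' @param spectrum An [action_spectrum()]; its wavelengths must all be
#'   present in the scan.
#' @param delta_nm Band width of the rectangle rule (nm).
#' @return A one-day (or multi-day) [uv_series()] labelled with the
#'   spectrum name.
#' @export
apply_action_spectrum <- function(day, spectrum, delta_nm = 1) {
  if (!inherits(day, "uv_spectral_day")) {
    out <- lapply(day, apply_action_spectrum, spectrum = spectrum,
                  delta_nm = delta_nm)
    return(Reduce(rbind_series, out))
  }
  missing_wl <- setdiff(spectrum$wavelengths, day$wavelengths)
  if (length(missing_wl)) {
    stop(sprintf("scan lacks wavelength(s) required by the action spectrum: %s",
                 paste(missing_wl, collapse = ", ")))
  }
  idx <- match(spectrum$wavelengths, day$wavelengths)
  w <- spectrum$weights * delta_nm
  vals <- as.numeric(day$spectra[, idx, drop = FALSE] %*% w)
  vals[!day$observed] <- NA_real_
  uv_series(matrix(vals, nrow = 1), day$date, day$grid, label = spectrum$name)
}
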