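#' Wavelength axis
#'
#' A wavelength axis is a strictly increasing numeric vector of band centers
#' in nanometers, one per spectral band.
#'
#' @param centers_nm numeric vector of band centers in nm, strictly increasing.
#' @return A numeric vector of class `wavelength_axis`.
#' @export
wavelength_axis <- function(centers_nm) {
  centers_nm <- as.numeric(centers_nm)
  if (length(centers_nm) < 1L)
    stop_bad_arg("a wavelength axis needs at least 1 band")
  if (anyNA(centers_nm) || !all(is.finite(centers_nm)) ||
      any(diff(centers_nm) <= 0))
    stop_bad_arg("wavelength axis must be strictly increasing and finite")
  structure(centers_nm, class = "wavelength_axis")
}

#' Default instrument wavelength axis
#'
#' The default axis mirrors a pushbroom NIR spectrograph with 256 bands
#' evenly spanning 874-1734 nm (about 3.4 nm between band centers).
#'
#' @param n_bands number of spectral bands.
#' @param lambda_min_nm,lambda_max_nm first and last band center in nm.
#' @return A `wavelength_axis`.
#' @export
default_wavelength_axis <- function(n_bands = 256L, lambda_min_nm = 874,
                                    lambda_max_nm = 1734) {
  if (lambda_min_nm >= lambda_max_nm)
    stop_bad_arg("lambda_min_nm must be below lambda_max_nm")
  wavelength_axis(seq(lambda_min_nm, lambda_max_nm, length.out = n_bands))
}

#' Nearest band index for a wavelength
#'
#' @param axis a `wavelength_axis`.
#' @param nm wavelength(s) in nm.
#' @return Integer band indices (1-based), one per element of `nm`.
#' @export
nearest_band <- function(axis, nm) {
  vapply(nm, function(w) which.min(abs(as.numeric(axis) - w)), integer(1))
}

#' @export
print.wavelength_axis <- function(x, ...) {
  cat(sprintf("<wavelength_axis> %d bands, %.1f-%.1f nm (median spacing %.2f nm)\n",
              length(x), x[1], x[length(x)], stats::median(diff(as.numeric(x)))))
  invisible(x)
}
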