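#' Truncate a dataset to a wavelength range
#'
#' Keeps the contiguous run of bands from the band nearest `lo_nm` through
#' the band nearest `hi_nm`, inclusive. On the default 256-band 874-1734 nm
#' axis, truncating to 972-1609 nm retains 190 bands — the noise-free window
#' used for berry spectra.
#'
#' @param ds a [spectral_dataset()].
#' @param lo_nm,hi_nm window endpoints in nm.
#' @return The truncated [spectral_dataset()].
#' @export
truncate_band_range <- function(ds, lo_nm, hi_nm) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (lo_nm > hi_nm) stop_bad_arg("lo_nm must not exceed hi_nm")
  nm <- as.numeric(ds$axis)
  # nearest band at each endpoint; exact ties resolve into the window
  d_lo <- abs(nm - lo_nm); i1 <- max(which(d_lo == min(d_lo)))
  d_hi <- abs(nm - hi_nm); i2 <- min(which(d_hi == min(d_hi)))
  if (i2 < i1) stop_bad_arg("empty band range after truncation")
  keep <- i1:i2
  spectral_dataset(ds$x[, keep, drop = FALSE],
                   wavelength_axis(as.numeric(ds$axis)[keep]),
                   y = ds$y, ids = ds$ids, deriv = ds$deriv)
}

#' Moving-average smoothing
#'
#' Centered boxcar mean along the spectral axis, applied independently per
#' spectrum. At the edges the window shrinks to the bands available within
#' the half-width, so the output keeps the input's length.
#'
#' @param ds a [spectral_dataset()].
#' @param window odd window width in bands (default 5).
#' @return The smoothed [spectral_dataset()].
#' @export
moving_average <- function(ds, window = 5L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  window <- as.integer(window)
  b <- n_bands(ds)
  if (window < 1L || window %% 2L == 0L || window > b)
    stop_bad_arg("window must be odd, >= 1 and <= number of bands")
  h <- (window - 1L) %/% 2L
  # b x b weight matrix: column j averages the bands within h of j
  w <- matrix(0, b, b)
  for (j in seq_len(b)) {
    idx <- max(1L, j - h):min(b, j + h)
    w[idx, j] <- 1 / length(idx)
  }
  spectral_dataset(ds$x %*% w, ds$axis, y = ds$y, ids = ds$ids,
                   deriv = ds$deriv)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Local least-squares polynomial convolution per spectrum; edges use the
#' polynomial fitted to the first/last full window. Derivatives are scaled by
#' the band spacing so their units are reflectance per nm^deriv; the axis
#' must be (approximately) evenly spaced.
#'
#' @param ds a [spectral_dataset()].
#' @param window odd window width in bands (default 9).
#' @param polyorder polynomial order (default 3), must be below `window`.
#' @param deriv derivative order 0, 1 or 2.
#' @return A [spectral_dataset()] whose `deriv` field records the order.
#' @export
savitzky_golay <- function(ds, window = 9L, polyorder = 3L, deriv = 0L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L || window < 3L || window > n_bands(ds))
    stop_bad_arg("window must be odd, >= 3 and <= number of bands")
  if (polyorder >= window) stop_bad_arg("polyorder must be below window")
  if (deriv < 0L || deriv > 2L || deriv > polyorder)
    stop_bad_arg("deriv must be in {0,1,2} and <= polyorder")
  spacing <- diff(as.numeric(ds$axis))
  if (max(spacing) / min(spacing) > 1.01)
    warning("axis spacing varies by more than 1%; derivative scaling uses the mean")
  out <- t(apply(ds$x, 1, signal::sgolayfilt, p = polyorder, n = window,
                 m = deriv, ts = mean(spacing)))
  spectral_dataset(out, ds$axis, y = ds$y, ids = ds$ids, deriv = deriv)
}
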