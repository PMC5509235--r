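#' Spectral dataset
#'
#' An n x b matrix of spectra with a shared wavelength axis, optional integer
#' class labels (origin codes) and sample identifiers. This is the container
#' every preprocessing and modeling step consumes and returns.
#'
#' @param x numeric matrix, one spectrum per row.
#' @param axis a [wavelength_axis()] with one entry per column of `x`.
#' @param y optional integer class labels, one per row.
#' @param ids optional sample identifiers, one per row.
#' @param deriv derivative order carried by the spectra (0 for reflectance).
#' @return An object of class `spectral_dataset` with fields `x`, `axis`,
#'   `y`, `ids` and `deriv`.
#' @export
spectral_dataset <- function(x, axis, y = NULL, ids = NULL, deriv = 0L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_bad_arg("spectra must not contain missing values")
  axis <- if (inherits(axis, "wavelength_axis")) axis else wavelength_axis(axis)
  if (ncol(x) != length(axis))
    stop_bad_arg("axis length (", length(axis), ") must match the number of ",
                 "spectral columns (", ncol(x), ")")
  if (!is.null(y)) {
    y <- as.integer(y)
    if (length(y) != nrow(x)) stop_bad_arg("one label per spectrum required")
    if (anyNA(y) || any(y < 1L)) stop_bad_arg("labels must be positive integers")
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  ids <- as.character(ids)
  if (length(ids) != nrow(x) || anyDuplicated(ids))
    stop_bad_arg("ids must be unique, one per spectrum")
  colnames(x) <- sprintf("%.2f", as.numeric(axis))
  rownames(x) <- ids
  structure(list(x = x, axis = axis, y = y, ids = ids,
                 deriv = as.integer(deriv)),
            class = "spectral_dataset")
}

#' Number of spectra / bands in a dataset
#' @param ds a `spectral_dataset`.
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$x)

#' @rdname n_samples
#' @export
n_bands <- function(ds) ncol(ds$x)

#' Subset a spectral dataset by sample ids or row indices
#'
#' @param ds a `spectral_dataset`.
#' @param ids character ids or integer row indices to keep, in the given order.
#' @return A `spectral_dataset` with the selected rows.
#' @export
subset_samples <- function(ds, ids) {
  idx <- if (is.character(ids)) match(ids, ds$ids) else as.integer(ids)
  if (anyNA(idx) || any(idx < 1L) || any(idx > n_samples(ds)))
    stop_bad_arg("unknown sample ids in subset")
  spectral_dataset(ds$x[idx, , drop = FALSE], ds$axis,
                   y = if (!is.null(ds$y)) ds$y[idx], ids = ds$ids[idx],
                   deriv = ds$deriv)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %d spectra x %d bands (%.1f-%.1f nm)",
              n_samples(x), n_bands(x), x$axis[1], x$axis[length(x$axis)]))
  if (x$deriv > 0L) cat(sprintf(", derivative order %d", x$deriv))
  cat("\n")
  if (!is.null(x$y)) {
    tab <- table(x$y)
    cat("  classes:", paste(sprintf("%s (n=%d)", names(tab), tab),
                            collapse = ", "), "\n")
  }
  invisible(x)
}
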