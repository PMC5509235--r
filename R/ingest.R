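#' Read a spectra table from XLSX or CSV
#'
#' Ingests deposited spectra tables (e.g. the supplementary calibration and
#' pixel-wise datasets) into a [spectral_dataset()]. Band columns are
#' recognized by numeric headers (wavelengths in nm, possibly decorated,
#' e.g. `"972.3"` or `"X972.3"`); a label and an id column can be named
#' explicitly via the column map since deposited layouts vary.
#'
#' @param path `.xlsx` or `.csv` file.
#' @param label_col optional name of the class-label column.
#' @param id_col optional name of the sample-id column.
#' @param sheet sheet index/name for XLSX input (default 1).
#' @return A [spectral_dataset()].
#' @export
read_spectra_table <- function(path, label_col = NULL, id_col = NULL,
                               sheet = 1) {
  if (!file.exists(path))
    stop_bad_arg("spectra table not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_bad_arg("reading XLSX requires the readxl package")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else if (ext == "csv") {
    read.csv(path, check.names = FALSE)
  } else stop_bad_arg("unsupported spectra table format: .", ext)
  nm <- suppressWarnings(as.numeric(sub("^[A-Za-z_]*", "", names(tab))))
  band_cols <- which(!is.na(nm))
  if (length(band_cols) < 2L)
    stop_bad_arg("fewer than 2 numeric wavelength columns found in ", path)
  ord <- band_cols[order(nm[band_cols])]
  x <- as.matrix(tab[, ord, drop = FALSE])
  storage.mode(x) <- "double"
  if (anyNA(x)) stop_bad_arg("missing values in the spectra block of ", path)
  y <- if (!is.null(label_col)) {
    if (!label_col %in% names(tab))
      stop_bad_arg("label column '", label_col, "' not found")
    as.integer(tab[[label_col]])
  }
  ids <- if (!is.null(id_col)) {
    if (!id_col %in% names(tab))
      stop_bad_arg("id column '", id_col, "' not found")
    as.character(tab[[id_col]])
  }
  spectral_dataset(x, wavelength_axis(sort(nm[band_cols])), y = y, ids = ids)
}

#' Write a spectral dataset as CSV
#'
#' Columns: `id`, `label` (when present), then one column per band named by
#' its wavelength in nm.
#'
#' @param ds a [spectral_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path) {
  stopifnot(inherits(ds, "spectral_dataset"))
  tab <- data.frame(id = ds$ids, check.names = FALSE)
  if (!is.null(ds$y)) tab$label <- ds$y
  tab <- cbind(tab, as.data.frame(ds$x, check.names = FALSE))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
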