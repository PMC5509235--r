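#' Write a hypercube as an ENVI raster
#'
#' Writes the band-sequential (BSQ) 32-bit float binary raster to `path` and
#' a plain-text ENVI header (with the wavelength list) to `<path>.hdr`.
#'
#' @param cube a [hypercube()].
#' @param path output data-file path (header written alongside as `.hdr`).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in seq_len(d[3])) {
    # ENVI stores each band row by row; R arrays are column-major
    writeBin(as.numeric(t(cube$values[, , k, drop = TRUE])), con, size = 4,
             endian = "little")
  }
  hdr <- c(
    "ENVI",
    "description = {berrytrace hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bsq",
    "byte order = 0",
    sprintf("calibrated = %d", as.integer(cube$calibrated)),
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(sprintf("%.4f", as.numeric(cube$axis)),
                                   collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' Read an ENVI raster into a hypercube
#'
#' Supports the subset of the format written by [write_envi()]: BSQ
#' interleave, 32-bit float, little-endian, wavelength list in the header.
#'
#' @param path data-file path (expects `<path>.hdr` alongside).
#' @return A [hypercube()].
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(path) || !file.exists(hdr_path))
    stop_bad_arg("ENVI data or header file not found at ", path)
  hdr <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  field <- function(name) {
    m <- regmatches(hdr, regexec(paste0(name, "\\s*=\\s*([^\n{]+)"), hdr))[[1]]
    if (length(m) < 2) stop_bad_arg("missing ENVI header field: ", name)
    trimws(m[2])
  }
  samples <- as.integer(field("samples"))
  lines <- as.integer(field("lines"))
  bands <- as.integer(field("bands"))
  if (as.integer(field("data type")) != 4L || field("interleave") != "bsq")
    stop_bad_arg("only BSQ float32 ENVI rasters are supported")
  wl <- regmatches(hdr, regexec("wavelength\\s*=\\s*\\{([^}]*)\\}", hdr))[[1]]
  if (length(wl) < 2) stop_bad_arg("missing wavelength list in ENVI header")
  axis <- wavelength_axis(as.numeric(strsplit(wl[2], ",")[[1]]))
  if (length(axis) != bands) stop_bad_arg("wavelength list does not match bands")
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- array(0, c(lines, samples, bands))
  for (k in seq_len(bands)) {
    band <- readBin(con, numeric(), n = samples * lines, size = 4,
                    endian = "little")
    vals[, , k] <- matrix(band, lines, samples, byrow = TRUE)
  }
  calib <- grepl("calibrated\\s*=\\s*1", hdr)
  hypercube(vals, axis, calibrated = calib)
}
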