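#' Hyperspectral cube
#'
#' A 3-D raster of `rows x cols x bands` holding either raw sensor counts or
#' calibrated relative reflectance, together with its wavelength axis.
#' Reflectance values slightly outside \[0, 1\] (sensor noise) are kept, not
#' clipped — clipping would bias derivative spectra — and can be inspected
#' with [reflectance_range_flags()].
#'
#' @param values 3-D numeric array, `rows x cols x bands`.
#' @param axis a [wavelength_axis()] of length `dim(values)[3]`.
#' @param calibrated logical; `TRUE` when values are reflectance.
#' @return An object of class `hypercube`.
#' @export
hypercube <- function(values, axis, calibrated = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop_bad_arg("values must be a rows x cols x bands array")
  axis <- if (inherits(axis, "wavelength_axis")) axis else wavelength_axis(axis)
  if (dim(values)[3] != length(axis))
    stop_bad_arg("axis length must equal the band dimension")
  structure(list(values = values, axis = axis,
                 calibrated = isTRUE(calibrated)),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hypercube> %d x %d pixels x %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], x$axis[1], x$axis[length(x$axis)],
              if (x$calibrated) "reflectance" else "raw counts"))
  invisible(x)
}

#' White/dark reference frames
#'
#' Reference frames for a pushbroom instrument: a white (high-reflectance
#' standard) and a dark (shutter-closed) frame, each `cols x bands`, applied
#' identically to every scan line. The white frame must exceed the dark frame
#' at every pixel/band.
#'
#' @param white,dark numeric `cols x bands` matrices of sensor counts.
#' @return An object of class `reference_frames`.
#' @export
reference_frames <- function(white, dark) {
  white <- as.matrix(white); dark <- as.matrix(dark)
  if (!identical(dim(white), dim(dark)))
    stop_bad_arg("white and dark frames must have identical dimensions")
  if (any(white <= dark))
    stop_bad_arg("white frame must exceed dark frame everywhere")
  structure(list(white = white, dark = dark), class = "reference_frames")
}

#' Reflectance calibration of a raw cube
#'
#' Converts raw counts to relative reflectance with the standard white/dark
#' correction `R = (raw - dark) / (white - dark)`, applied per column and
#' band. A zero denominator anywhere is an error (reporting the offending
#' coordinates), never a silent `NaN`.
#'
#' @param raw a raw-count [hypercube()].
#' @param refs a [reference_frames()] whose frames are `cols x bands`.
#' @return A calibrated [hypercube()] of reflectance.
#' @export
calibrate_cube <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"), inherits(refs, "reference_frames"))
  if (raw$calibrated) stop_bad_arg("cube is already calibrated")
  d <- dim(raw$values)
  if (!identical(dim(refs$white), c(d[2], d[3])))
    stop_bad_arg("reference frames must be cols x bands matrices matching the cube")
  den <- refs$white - refs$dark
  zero <- which(den == 0, arr.ind = TRUE)
  if (nrow(zero) > 0) {
    show <- head(zero, 5)
    stop_bad_arg("white - dark is zero at (col, band): ",
                 paste(sprintf("(%d,%d)", show[, 1], show[, 2]), collapse = " "),
                 if (nrow(zero) > 5) sprintf(" and %d more", nrow(zero) - 5))
  }
  refl <- array(0, d)
  for (k in seq_len(d[3])) {
    slice <- matrix(raw$values[, , k], d[1], d[2])
    refl[, , k] <- sweep(sweep(slice, 2, refs$dark[, k]), 2, den[, k], "/")
  }
  hypercube(refl, raw$axis, calibrated = TRUE)
}

#' Count out-of-range reflectance values
#'
#' @param cube a calibrated [hypercube()].
#' @return Named integer vector with counts of values below 0 and above 1.
#' @export
reflectance_range_flags <- function(cube) {
  stopifnot(inherits(cube, "hypercube"), cube$calibrated)
  c(below_zero = sum(cube$values < 0), above_one = sum(cube$values > 1))
}

#' Background mask from mean reflectance
#'
#' Flags foreground (sample) pixels as those whose mean reflectance over a
#' stated wavelength window exceeds a threshold. Berries are bright against
#' the dark stage across 1000-1300 nm, the default window.
#'
#' @param cube a calibrated [hypercube()].
#' @param threshold reflectance threshold (default 0.15).
#' @param window_nm length-2 window in nm over which the mean is taken.
#' @return Logical `rows x cols` matrix, `TRUE` for foreground.
#' @export
mask_background <- function(cube, threshold = 0.15, window_nm = c(1000, 1300)) {
  stopifnot(inherits(cube, "hypercube"))
  if (!cube$calibrated) stop_bad_arg("mask_background needs a calibrated cube")
  bands <- which(cube$axis >= min(window_nm) & cube$axis <= max(window_nm))
  if (length(bands) == 0) bands <- nearest_band(cube$axis, mean(window_nm))
  mu <- apply(cube$values[, , bands, drop = FALSE], c(1, 2), mean)
  mask <- mu > threshold
  if (!any(mask))
    stop_bad_arg("empty foreground: no pixel exceeds threshold ", threshold)
  mask
}

#' Segment foreground objects
#'
#' Labels 4-connected components of a binary mask, removes components below
#' a minimum pixel count, and relabels the survivors 1..K in raster-scan
#' order (row by row) of each object's first pixel.
#'
#' @param mask logical `rows x cols` matrix (`TRUE` = foreground).
#' @param min_size minimum component size in pixels (default 20).
#' @return List with `labels` (integer matrix, 0 = background) and `objects`
#'   (data frame: `object_id`, `pixel_count`, `centroid_row`, `centroid_col`,
#'   1-based pixel coordinates).
#' @export
segment_objects <- function(mask, min_size = 20L) {
  if (!is.matrix(mask)) stop_bad_arg("mask must be a matrix")
  mask <- mask != 0
  lab <- EBImage::bwlabel(mask * 1L)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_size)
  if (length(keep) == 0L) {
    warning("no objects of at least ", min_size, " pixels found")
    return(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                objects = data.frame(object_id = integer(), pixel_count = integer(),
                                     centroid_row = numeric(), centroid_col = numeric())))
  }
  # raster-scan (row-major) order of each surviving component's first pixel
  first_pos <- vapply(keep, function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    min((px[, 1] - 1) * ncol(mask) + px[, 2])
  }, numeric(1))
  keep <- keep[order(first_pos)]
  out <- matrix(0L, nrow(mask), ncol(mask))
  objects <- data.frame(object_id = integer(), pixel_count = integer(),
                        centroid_row = numeric(), centroid_col = numeric())
  for (new_id in seq_along(keep)) {
    px <- which(lab == keep[new_id], arr.ind = TRUE)
    out[px] <- new_id
    objects <- rbind(objects, data.frame(
      object_id = new_id, pixel_count = nrow(px),
      centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2])))
  }
  list(labels = out, objects = objects)
}

#' Extract per-pixel spectra for labeled objects
#'
#' One row per foreground pixel; spectra are copied out of the cube.
#'
#' @param cube a calibrated [hypercube()].
#' @param labels integer label matrix from [segment_objects()].
#' @param class_map optional named vector mapping object id to class id.
#' @return An object of class `pixel_spectra`: list with `info` (data frame
#'   `row`, `col`, `object_id`, `class_id`), `x` (pixel x band reflectance
#'   matrix) and `axis`.
#' @export
extract_pixel_spectra <- function(cube, labels, class_map = NULL) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$values)
  if (!identical(dim(labels), d[1:2]))
    stop_bad_arg("label image shape must match the cube's spatial shape")
  px <- which(labels > 0L, arr.ind = TRUE)
  if (nrow(px) == 0L) stop_bad_arg("no labeled foreground pixels")
  ord <- order((px[, 1] - 1) * d[2] + px[, 2])
  px <- px[ord, , drop = FALSE]
  oid <- labels[px]
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  x <- flat[(px[, 2] - 1) * d[1] + px[, 1], , drop = FALSE]
  colnames(x) <- sprintf("%.2f", as.numeric(cube$axis))
  cls <- if (is.null(class_map)) rep(NA_integer_, length(oid))
         else as.integer(class_map[as.character(oid)])
  structure(list(info = data.frame(row = px[, 1], col = px[, 2],
                                   object_id = as.integer(oid), class_id = cls),
                 x = x, axis = cube$axis),
            class = "pixel_spectra")
}

#' @export
print.pixel_spectra <- function(x, ...) {
  cat(sprintf("<pixel_spectra> %d pixels x %d bands, %d objects\n",
              nrow(x$x), ncol(x$x), length(unique(x$info$object_id))))
  invisible(x)
}

#' Object-wise mean spectra
#'
#' Averages the spectra of all pixels of each object (berry) into one sample
#' spectrum — the object-wise representation used for modeling.
#'
#' @param px a `pixel_spectra` table from [extract_pixel_spectra()].
#' @param min_pixels drop objects with fewer pixels than this (default 1).
#' @return A [spectral_dataset()] with one row per object; ids are object
#'   ids, labels the object class ids (when known), and a `pixel_count`
#'   attribute records per-object pixel counts.
#' @export
mean_spectra <- function(px, min_pixels = 1L) {
  stopifnot(inherits(px, "pixel_spectra"))
  if (nrow(px$x) == 0L) stop_bad_arg("empty pixel table")
  oid <- px$info$object_id
  counts <- table(oid)
  keep <- names(counts)[counts >= min_pixels]
  rows <- oid %in% as.integer(keep)
  means <- rowsum(px$x[rows, , drop = FALSE], oid[rows]) /
    as.vector(counts[as.character(sort(unique(oid[rows])))])
  ids <- rownames(means)
  cls <- vapply(ids, function(i) px$info$class_id[match(as.integer(i), oid)],
                integer(1))
  ds <- spectral_dataset(means, px$axis,
                         y = if (!anyNA(cls)) cls else NULL, ids = ids)
  attr(ds, "pixel_count") <- as.integer(counts[ids])
  ds
}
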