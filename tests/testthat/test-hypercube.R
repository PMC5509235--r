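make_refs <- function(n_cols, n_bands, white = 110, dark = 10) {
  reference_frames(matrix(white, n_cols, n_bands),
                   matrix(dark, n_cols, n_bands))
}

test_that("calibration maps dark to 0, white to 1 and interpolates linearly", {
  ax <- wavelength_axis(c(1000, 1100, 1200))
  refs <- make_refs(4, 3)
  dark_cube <- hypercube(array(10, c(2, 4, 3)), ax)
  white_cube <- hypercube(array(110, c(2, 4, 3)), ax)
  mid_cube <- hypercube(array(30, c(2, 4, 3)), ax)
  expect_equal(calibrate_cube(dark_cube, refs)$values, array(0, c(2, 4, 3)))
  expect_equal(calibrate_cube(white_cube, refs)$values, array(1, c(2, 4, 3)))
  expect_equal(calibrate_cube(mid_cube, refs)$values,
               array(0.2, c(2, 4, 3)))
  expect_true(calibrate_cube(mid_cube, refs)$calibrated)
})

test_that("zero white-dark denominator is a coordinate-reporting error", {
  ax <- wavelength_axis(c(1000, 1100))
  white <- matrix(110, 3, 2); dark <- matrix(10, 3, 2)
  white[2, 1] <- 10  # equals dark there
  expect_error(reference_frames(white, dark), "exceed")
  # bypass the constructor guard to exercise the calibration check itself
  refs <- structure(list(white = white, dark = dark),
                    class = "reference_frames")
  raw <- hypercube(array(50, c(2, 3, 2)), ax)
  expect_error(calibrate_cube(raw, refs), "\\(2,1\\)")
})

test_that("calibration is invariant to consistent affine re-exposure", {
  ax <- wavelength_axis(seq(1000, 1090, by = 10))
  set.seed(1)
  refl <- array(runif(4 * 5 * 10, 0.1, 0.9), c(4, 5, 10))
  white <- matrix(runif(5 * 10, 90, 120), 5, 10)
  dark <- matrix(runif(5 * 10, 5, 15), 5, 10)
  build_raw <- function(w, d) {
    raw <- array(0, c(4, 5, 10))
    for (k in 1:10)
      raw[, , k] <- sweep(sweep(refl[, , k], 2, w[, k] - d[, k], "*"),
                          2, d[, k], "+")
    raw
  }
  r1 <- calibrate_cube(hypercube(build_raw(white, dark), ax),
                       reference_frames(white, dark))
  # doubled gain, shifted offset, consistently in frames and raw
  r2 <- calibrate_cube(hypercube(build_raw(2 * white + 7, 2 * dark + 7), ax),
                       reference_frames(2 * white + 7, 2 * dark + 7))
  expect_equal(r1$values, refl, tolerance = 1e-12)
  expect_equal(r2$values, refl, tolerance = 1e-12)
})

test_that("background mask recovers the truth foreground on a clean scene", {
  spec <- small_spec()
  sc <- render_scene(spec, default_origin_models(noise_sd = 0, scatter_sd = 0),
                     n_objects_per_class = 2, seed = 4,
                     radius_range = c(4, 7))
  refl <- calibrate_cube(sc$raw, sc$refs)
  mask <- mask_background(refl, threshold = 0.15)
  expect_identical(mask, sc$truth$label_image > 0)
  expect_true(all(mask_background(refl, threshold = 0)))
  expect_error(mask_background(refl, threshold = 2), "empty foreground")
  expect_error(mask_background(sc$raw), "calibrated")
})

test_that("segmentation matches a flood-fill oracle and filters small blobs", {
  mask <- matrix(FALSE, 12, 15)
  mask[2:5, 2:6] <- TRUE         # 20 px blob
  mask[8:11, 9:14] <- TRUE       # 24 px blob
  mask[1, 15] <- TRUE            # 1 px speck
  seg <- segment_objects(mask, min_size = 5)
  oracle <- flood_fill_components(mask)
  expect_equal(nrow(seg$objects), 2)
  expect_equal(seg$objects$pixel_count, c(20L, 24L))
  # labels 1..K in raster-scan order of first pixel
  expect_equal(seg$labels[2, 2], 1L)
  expect_equal(seg$labels[8, 9], 2L)
  # same partition as the oracle on the surviving blobs
  for (k in 1:2) {
    px <- which(seg$labels == k)
    expect_length(unique(oracle[px]), 1)
  }
  expect_warning(segment_objects(mask, min_size = 100), "no objects")
})

test_that("segmenting a synthetic scene recovers truth objects and centroids", {
  spec <- acquisition_spec(90, 120, 12)
  sc <- render_scene(spec, default_origin_models(noise_sd = 0, scatter_sd = 0),
                     n_objects_per_class = 3, seed = 2,
                     radius_range = c(4, 7))
  refl <- calibrate_cube(sc$raw, sc$refs)
  seg <- segment_objects(mask_background(refl), min_size = 20)
  expect_equal(nrow(seg$objects), 12)
  tr <- sc$truth$object_table
  # raster-scan relabeling can permute ids; match by nearest centroid
  for (i in seq_len(12)) {
    d <- sqrt((tr$centroid_row - seg$objects$centroid_row[i])^2 +
                (tr$centroid_col - seg$objects$centroid_col[i])^2)
    expect_lt(min(d), 0.5)
  }
})

test_that("pixel extraction is exhaustive, copied and consistent with means", {
  spec <- small_spec()
  sc <- render_scene(spec, n_objects_per_class = 2, seed = 7, radius_range = c(4, 7))
  refl <- calibrate_cube(sc$raw, sc$refs)
  labels <- sc$truth$label_image
  class_map <- stats::setNames(sc$truth$object_table$class_id,
                               sc$truth$object_table$object_id)
  px <- extract_pixel_spectra(refl, labels, class_map)
  expect_equal(nrow(px$x), sum(labels > 0))
  expect_false(any(duplicated(px$info[, c("row", "col")])))
  # pixel conservation: per-object counts sum to the mask count
  expect_equal(sum(table(px$info$object_id)), sum(labels > 0))
  # spectra are copies of the cube values
  i <- 17
  expect_equal(unname(px$x[i, ]),
               refl$values[px$info$row[i], px$info$col[i], ])
  # mean_spectra equals the per-object average of extracted rows
  ms <- mean_spectra(px)
  for (oid in unique(px$info$object_id)) {
    rows <- px$info$object_id == oid
    expect_equal(unname(ms$x[as.character(oid), ]),
                 unname(colMeans(px$x[rows, , drop = FALSE])))
  }
  expect_equal(ms$y, unname(class_map[ms$ids]))
  expect_error(extract_pixel_spectra(refl, labels[1:10, ]), "shape")
})

test_that("single- and multi-pixel object means obey linearity", {
  ax <- wavelength_axis(c(1000, 1100, 1200))
  s <- c(0.2, 0.4, 0.6)
  cube <- hypercube(array(0, c(1, 3, 3)), ax, calibrated = TRUE)
  cube$values[1, 1, ] <- s
  cube$values[1, 2, ] <- s
  cube$values[1, 3, ] <- 3 * s
  labels <- matrix(c(1L, 2L, 2L), 1, 3)
  ms <- mean_spectra(extract_pixel_spectra(cube, labels))
  expect_equal(unname(ms$x["1", ]), s)
  expect_equal(unname(ms$x["2", ]), 2 * s)
})

test_that("mean_spectra commutes with band truncation", {
  spec <- small_spec()
  sc <- render_scene(spec, n_objects_per_class = 2, seed = 8, radius_range = c(4, 7))
  refl <- calibrate_cube(sc$raw, sc$refs)
  px <- extract_pixel_spectra(refl, sc$truth$label_image)
  ms_then_trunc <- truncate_band_range(mean_spectra(px), 1000, 1500)
  # truncate the cube first, then average
  keep <- nearest_band(refl$axis, 1000):nearest_band(refl$axis, 1500)
  cube_t <- hypercube(refl$values[, , keep, drop = FALSE],
                      wavelength_axis(as.numeric(refl$axis)[keep]),
                      calibrated = TRUE)
  trunc_then_ms <- mean_spectra(extract_pixel_spectra(cube_t,
                                                      sc$truth$label_image))
  expect_equal(ms_then_trunc$x, trunc_then_ms$x, tolerance = 1e-12)
})

test_that("ENVI write/read round-trips a cube to float32 precision", {
  spec <- acquisition_spec(30, 40, 5, 1000, 1400, 1000)
  sc <- render_scene(spec, n_objects_per_class = 1, seed = 3,
                     radius_range = c(2, 3))
  path <- tempfile(fileext = ".dat")
  write_envi(sc$raw, path)
  back <- read_envi(path)
  expect_equal(back$values, sc$raw$values, tolerance = 1e-6)
  expect_equal(as.numeric(back$axis), as.numeric(sc$raw$axis),
               tolerance = 1e-4)
  expect_false(back$calibrated)
  unlink(c(path, paste0(path, ".hdr")))
})
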