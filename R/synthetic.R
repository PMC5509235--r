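#' Acquisition geometry for synthetic scenes
#'
#' Mirrors a line-scan NIR instrument: a frame 320 spatial pixels wide with
#' 256 spectral bands spanning 874-1734 nm; the number of scan lines is free.
#'
#' @param n_rows scan lines (spatial rows).
#' @param n_cols spatial pixels per line.
#' @param n_bands spectral bands.
#' @param lambda_min_nm,lambda_max_nm first/last band center in nm.
#' @param bit_depth_max white-level sensor counts.
#' @return An object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_rows = 240L, n_cols = 320L, n_bands = 256L,
                             lambda_min_nm = 874, lambda_max_nm = 1734,
                             bit_depth_max = 4095) {
  if (n_bands < 2L) stop_bad_arg("n_bands must be at least 2")
  if (lambda_min_nm >= lambda_max_nm)
    stop_bad_arg("lambda_min_nm must be below lambda_max_nm")
  if (bit_depth_max <= 0) stop_bad_arg("bit_depth_max must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_bands = as.integer(n_bands),
                 lambda_min_nm = lambda_min_nm, lambda_max_nm = lambda_max_nm,
                 bit_depth_max = bit_depth_max),
            class = "acquisition_spec")
}

#' Wavelength axis implied by an acquisition spec
#' @param spec an [acquisition_spec()].
#' @return A [wavelength_axis()].
#' @export
spec_axis <- function(spec) {
  default_wavelength_axis(spec$n_bands, spec$lambda_min_nm, spec$lambda_max_nm)
}

#' Reflectance model for one geographic origin
#'
#' A class endmember is a smooth baseline with Gaussian absorption dips at
#' the NIR bands typical of berry tissue: near 995 nm (N-H overtones of
#' protein), 1200 nm (C-H stretch of starch/lipid) and 1465 nm (water).
#' Origins differ only by a small additive offset and mild scaling of the
#' dip depths, so classes overlap in score space but remain clustered.
#'
#' @param class_id integer origin code (1-4 in the default scene).
#' @param baseline_reflectance function of wavelength (nm) returning the
#'   dip-free reflectance in (0, 1).
#' @param absorption_centers_nm dip centers in nm.
#' @param absorption_depths dip depths (reflectance units, in \[0, 1\)).
#' @param absorption_widths_nm Gaussian sigma of each dip in nm.
#' @param offset_shift additive class offset (reflectance units).
#' @param noise_sd per-pixel, per-band Gaussian noise sd (reflectance units).
#' @param scatter_sd sd of the per-object multiplicative scatter factor.
#' @return An object of class `origin_model`.
#' @export
origin_model <- function(class_id,
                         baseline_reflectance = function(nm) 0.40 + 1.5e-4 * (nm - 874),
                         absorption_centers_nm = c(995, 1200, 1465),
                         absorption_depths = c(0.06, 0.10, 0.16),
                         absorption_widths_nm = c(26, 38, 48),
                         offset_shift = 0,
                         noise_sd = 0.01,
                         scatter_sd = 0.02) {
  if (length(absorption_centers_nm) != length(absorption_depths) ||
      length(absorption_depths) != length(absorption_widths_nm))
    stop_bad_arg("centers, depths and widths must have equal length")
  if (any(absorption_depths < 0) || any(absorption_depths >= 1))
    stop_bad_arg("absorption depths must lie in [0, 1)")
  if (any(absorption_widths_nm <= 0)) stop_bad_arg("widths must be positive")
  if (noise_sd < 0 || scatter_sd < 0) stop_bad_arg("noise sds must be >= 0")
  structure(list(class_id = as.integer(class_id),
                 baseline_reflectance = baseline_reflectance,
                 absorption_centers_nm = absorption_centers_nm,
                 absorption_depths = absorption_depths,
                 absorption_widths_nm = absorption_widths_nm,
                 offset_shift = offset_shift, noise_sd = noise_sd,
                 scatter_sd = scatter_sd),
            class = "origin_model")
}

#' Default four-origin models
#'
#' Four origin models sharing one baseline and dip set, separated by small
#' additive offsets and depth scalings. `separation` scales both: 1 gives
#' the default overlapping-but-clustered classes, 0 gives identical classes
#' (a chance-level null), larger values give well-separated classes.
#'
#' @param separation non-negative multiplier on the between-class contrasts.
#' @param noise_sd,scatter_sd noise parameters passed to every model.
#' @return List of four [origin_model()] objects (class ids 1-4).
#' @export
default_origin_models <- function(separation = 1, noise_sd = 0.01,
                                  scatter_sd = 0.02) {
  if (separation < 0) stop_bad_arg("separation must be >= 0")
  offsets <- c(0, 0.018, -0.018, 0.032) * separation
  depth_scale <- 1 + c(0, 0.05, -0.05, 0.08) * separation
  lapply(1:4, function(k) {
    base_depths <- c(0.06, 0.10, 0.16)
    origin_model(class_id = k,
                 absorption_depths = pmin(base_depths * depth_scale[k], 0.95),
                 offset_shift = offsets[k],
                 noise_sd = noise_sd, scatter_sd = scatter_sd)
  })
}

#' Clean endmember spectrum of an origin model
#'
#' Samples the model's noise-free reflectance on a wavelength axis:
#' baseline + offset minus the sum of Gaussian dips. Errors if the result
#' leaves (0, 1).
#'
#' @param model an [origin_model()].
#' @param axis a [wavelength_axis()].
#' @return Numeric reflectance vector, one value per band.
#' @export
make_endmember <- function(model, axis) {
  stopifnot(inherits(model, "origin_model"))
  nm <- as.numeric(axis)
  r <- model$baseline_reflectance(nm) + model$offset_shift
  for (i in seq_along(model$absorption_centers_nm)) {
    r <- r - model$absorption_depths[i] *
      exp(-0.5 * ((nm - model$absorption_centers_nm[i]) /
                    model$absorption_widths_nm[i])^2)
  }
  if (any(r <= 0) || any(r >= 1))
    stop_bad_arg("endmember reflectance leaves (0, 1); reduce depths or offset")
  r
}

#' Object-wise sample library (skips image rendering)
#'
#' Draws `n_per_class` sample spectra per origin directly from the origin
#' models: each sample is its class endmember times a per-sample scatter
#' factor `N(1, scatter_sd)` plus i.i.d. band noise `N(0, noise_sd)`. This is
#' the object-wise shortcut used for model benchmarking; the full image path
#' goes through [render_scene()].
#'
#' @param models list of [origin_model()] objects.
#' @param n_per_class samples per origin (default 300, giving 1200 for the
#'   default four-origin setup).
#' @param axis wavelength axis (default: the full 256-band instrument axis).
#' @param noise_sd,scatter_sd overrides; `NULL` uses each model's own value.
#' @param seed integer seed fixing all randomness.
#' @return A [spectral_dataset()] with class labels and ids `C<k>_<j>`.
#' @export
make_sample_library <- function(models, n_per_class = 300L,
                                axis = default_wavelength_axis(),
                                noise_sd = NULL, scatter_sd = NULL, seed = 1L) {
  if (n_per_class < 1L) stop_bad_arg("n_per_class must be >= 1")
  with_seed(seed, {
    rows <- list(); ys <- integer(); ids <- character()
    for (m in models) {
      e <- make_endmember(m, axis)
      nsd <- if (is.null(noise_sd)) m$noise_sd else noise_sd
      ssd <- if (is.null(scatter_sd)) m$scatter_sd else scatter_sd
      scat <- rnorm(n_per_class, 1, ssd)
      noise <- matrix(rnorm(n_per_class * length(axis), 0, nsd),
                      n_per_class, length(axis))
      rows[[length(rows) + 1L]] <- outer(scat, e) + noise
      ys <- c(ys, rep(m$class_id, n_per_class))
      ids <- c(ids, sprintf("C%d_%03d", m$class_id, seq_len(n_per_class)))
    }
    spectral_dataset(do.call(rbind, rows), axis, y = ys, ids = ids)
  })
}

# place n non-overlapping ellipses inside an n_rows x n_cols frame;
# returns a data frame of centers/semi-axes/orientations or errors
place_ellipses <- function(n_rows, n_cols, n, radius_range, max_attempts) {
  placed <- data.frame(r = numeric(), c = numeric(), a = numeric(),
                       b = numeric(), phi = numeric())
  attempts <- 0L
  while (nrow(placed) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_bad_arg("could not place ", n, " non-overlapping objects in ",
                   max_attempts, " attempts; enlarge the frame or shrink radii")
    a <- runif(1, radius_range[1], radius_range[2])
    b <- runif(1, radius_range[1], radius_range[2])
    rmax <- max(a, b)
    if (2 * rmax + 4 >= min(n_rows, n_cols)) next  # cannot fit in the frame
    cr <- runif(1, rmax + 2, n_rows - rmax - 1)
    cc <- runif(1, rmax + 2, n_cols - rmax - 1)
    # conservative bounding-circle test with a 2 px margin
    ok <- all(sqrt((placed$r - cr)^2 + (placed$c - cc)^2) >
                (pmax(placed$a, placed$b) + rmax + 2))
    if (ok)
      placed <- rbind(placed, data.frame(r = cr, c = cc, a = a, b = b,
                                         phi = runif(1, 0, pi)))
  }
  placed
}

#' Render a synthetic scene: raw cube, reference frames and ground truth
#'
#' Places non-overlapping filled ellipses ("berries") of each origin class on
#' a dark stage, builds the clean reflectance cube (endmember times a
#' per-object scatter factor; constant low background), and inverts the
#' white/dark calibration to produce the raw counts:
#' `raw = dark + (clean + noise) * (white - dark)`, so calibrating the
#' outputs recovers the clean cube up to the injected noise exactly.
#'
#' @param spec an [acquisition_spec()].
#' @param models list of [origin_model()] objects.
#' @param n_objects_per_class objects per class to place.
#' @param seed integer seed fixing all randomness.
#' @param radius_range ellipse semi-axis range in pixels.
#' @param background_reflectance stage reflectance (flat, default 0.05).
#' @param max_attempts placement attempts before giving up.
#' @return List with `raw` ([hypercube()]), `refs` ([reference_frames()]) and
#'   `truth` (list: `label_image`, `object_table`, `clean` cube).
#' @export
render_scene <- function(spec, models = default_origin_models(),
                         n_objects_per_class = 3L, seed = 1L,
                         radius_range = c(8, 14),
                         background_reflectance = 0.05,
                         max_attempts = 5000L) {
  stopifnot(inherits(spec, "acquisition_spec"))
  axis <- spec_axis(spec)
  nb <- spec$n_bands; nr <- spec$n_rows; nc <- spec$n_cols
  with_seed(seed, {
    n_obj <- n_objects_per_class * length(models)
    ell <- place_ellipses(nr, nc, n_obj, radius_range, max_attempts)
    classes <- rep(vapply(models, `[[`, integer(1), "class_id"),
                   each = n_objects_per_class)
    label <- matrix(0L, nr, nc)
    rows_idx <- matrix(rep(seq_len(nr), nc), nr, nc)
    cols_idx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    for (i in seq_len(n_obj)) {
      dr <- rows_idx - ell$r[i]; dc <- cols_idx - ell$c[i]
      u <- dr * cos(ell$phi[i]) + dc * sin(ell$phi[i])
      v <- -dr * sin(ell$phi[i]) + dc * cos(ell$phi[i])
      inside <- (u / ell$a[i])^2 + (v / ell$b[i])^2 <= 1
      label[inside] <- i
    }
    endm <- lapply(models, make_endmember, axis = axis)
    names(endm) <- vapply(models, `[[`, integer(1), "class_id")
    scat <- rnorm(n_obj, 1, vapply(models, `[[`, numeric(1), "scatter_sd")[
      match(classes, as.integer(names(endm)))])
    flat <- matrix(background_reflectance, nr * nc, nb)
    for (i in seq_len(n_obj)) {
      px <- which(label == i)
      spec_i <- pmin(pmax(endm[[as.character(classes[i])]] * scat[i], 1e-4),
                     1 - 1e-4)
      flat[px, ] <- matrix(spec_i, length(px), nb, byrow = TRUE)
    }
    clean <- array(flat, c(nr, nc, nb))
    # smooth, strictly positive reference frames (cols x bands)
    band_prof <- 0.88 + 0.08 * sin(pi * seq(0, 1, length.out = nb))
    col_prof <- 0.95 + 0.05 * cos(pi * seq(-1, 1, length.out = nc))
    white <- spec$bit_depth_max * outer(col_prof, band_prof)
    dark <- 0.02 * spec$bit_depth_max *
      (1 + 0.1 * outer(seq(0, 1, length.out = nc), seq(0, 1, length.out = nb)))
    noise_sd <- vapply(models, `[[`, numeric(1), "noise_sd")[1]
    raw <- array(0, c(nr, nc, nb))
    for (k in seq_len(nb)) {
      refl_k <- clean[, , k]
      if (noise_sd > 0)
        refl_k <- refl_k + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
      raw[, , k] <- sweep(sweep(refl_k, 2, white[, k] - dark[, k], "*"),
                          2, dark[, k], "+")
    }
    object_table <- data.frame(
      object_id = seq_len(n_obj), class_id = classes,
      centroid_row = vapply(seq_len(n_obj), function(i)
        mean(rows_idx[label == i]), numeric(1)),
      centroid_col = vapply(seq_len(n_obj), function(i)
        mean(cols_idx[label == i]), numeric(1)),
      pixel_count = vapply(seq_len(n_obj), function(i)
        sum(label == i), numeric(1)))
    list(raw = hypercube(raw, axis, calibrated = FALSE),
         refs = reference_frames(white, dark),
         truth = list(label_image = label, object_table = object_table,
                      clean = hypercube(clean, axis, calibrated = TRUE)))
  })
}
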