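#' Principal component analysis of spectra
#'
#' Column-mean-centered (unscaled) PCA via the singular value decomposition.
#' The sign of each loading vector is fixed so its largest-magnitude entry is
#' positive, making results deterministic across platforms.
#'
#' @param ds a [spectral_dataset()].
#' @param k number of components to keep.
#' @return An object of class `pca_result` with `loadings` (bands x k,
#'   orthonormal columns), `scores` (n x k), `explained_ratio` (first k
#'   variance fractions; the fractions over all components sum to 1),
#'   `mean_spectrum`, `axis` and `total_variance`.
#' @export
fit_pca <- function(ds, k = 5L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- n_samples(ds); b <- n_bands(ds); k <- as.integer(k)
  if (n < 2L) stop_bad_arg("PCA needs at least 2 samples")
  if (k < 1L || k > min(n - 1L, b))
    stop_bad_arg("k must be in 1..min(n-1, bands)")
  pc <- prcomp(ds$x, center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  if (total <= .Machine$double.eps)
    stop_bad_arg("data has zero variance; PCA undefined")
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(load) <- sprintf("%.2f", as.numeric(ds$axis))
  structure(list(loadings = load, scores = scores,
                 explained_ratio = (pc$sdev^2 / total)[seq_len(k)],
                 mean_spectrum = pc$center, axis = ds$axis,
                 total_variance = total, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d components, cumulative explained variance %.2f%%\n",
              x$k, 100 * sum(x$explained_ratio)))
  invisible(x)
}

# Interior strict local extrema of a numeric vector. Runs of equal values
# (to within a small tolerance relative to the curve's magnitude, so
# numerically constant curves have no extrema) are compressed; an extremal
# plateau contributes its leftmost band. Runs touching either edge are never
# extrema.
local_extrema <- function(v, rel_tol = 1e-8) {
  n <- length(v)
  if (n < 3L) return(integer())
  eps <- rel_tol * max(abs(v))
  if (!is.finite(eps)) return(integer())
  steps <- diff(v)
  run_start <- c(1L, which(abs(steps) > eps) + 1L)
  run_val <- v[run_start]
  m <- length(run_val)
  if (m < 3L) return(integer())
  interior <- 2:(m - 1L)
  is_max <- run_val[interior] > run_val[interior - 1L] &
    run_val[interior] > run_val[interior + 1L]
  is_min <- run_val[interior] < run_val[interior - 1L] &
    run_val[interior] < run_val[interior + 1L]
  sort(run_start[interior[is_max | is_min]])
}

#' Selected characteristic wavelengths
#'
#' @param band_indices integer band indices into `axis`.
#' @param axis the [wavelength_axis()] the indices refer to.
#' @param source `"pca_loadings"` or `"second_derivative"`.
#' @param params list of the selection settings used.
#' @return An object of class `selected_wavelengths` (indices sorted,
#'   de-duplicated, with matching nm values).
#' @export
selected_wavelengths <- function(band_indices, axis, source, params = list()) {
  idx <- sort(unique(as.integer(band_indices)))
  if (length(idx) && (min(idx) < 1L || max(idx) > length(axis)))
    stop_bad_arg("band indices out of range for the axis")
  structure(list(band_indices = idx,
                 wavelengths_nm = as.numeric(axis)[idx],
                 source = match.arg(source, c("pca_loadings", "second_derivative")),
                 params = params),
            class = "selected_wavelengths")
}

#' @export
print.selected_wavelengths <- function(x, ...) {
  cat(sprintf("<selected_wavelengths> %d bands from %s: %s\n",
              length(x$band_indices), x$source,
              paste(sprintf("%.0f", x$wavelengths_nm), collapse = ", ")))
  invisible(x)
}

#' Characteristic wavelengths from PCA loading extrema
#'
#' For each of the first `n_components` loading vectors, finds the interior
#' local peaks and valleys of the wavelength-loading curve, keeps those with
#' `|loading| >= threshold`, and unions the picks over components. An
#' optional `top_m` cap keeps the `m` picks with the largest absolute
#' loading (over all contributing components).
#'
#' @param pca a [fit_pca()] result.
#' @param n_components loading vectors to scan (default: all fitted).
#' @param threshold minimum absolute loading (default 0, i.e. all extrema).
#' @param top_m optional cap on the number of selected wavelengths.
#' @return A [selected_wavelengths()] with source `"pca_loadings"`.
#' @export
pick_loading_extrema <- function(pca, n_components = pca$k, threshold = 0,
                                 top_m = NULL) {
  stopifnot(inherits(pca, "pca_result"))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > pca$k)
    stop_bad_arg("n_components must be in 1..k")
  if (threshold < 0) stop_bad_arg("threshold must be >= 0")
  best <- numeric(0)  # per selected band: largest |loading| among components
  for (j in seq_len(n_components)) {
    v <- pca$loadings[, j]
    ext <- local_extrema(v)
    ext <- ext[abs(v[ext]) >= threshold]
    for (i in ext) {
      key <- as.character(i)
      best[key] <- max(best[key], abs(v[i]), na.rm = TRUE)
    }
  }
  idx <- as.integer(names(best))
  if (!is.null(top_m) && length(idx) > top_m)
    idx <- idx[rank(-best, ties.method = "first") <= top_m]
  if (length(idx) == 0L) warning("no loading extrema pass the threshold")
  selected_wavelengths(idx, pca$axis, "pca_loadings",
                       params = list(n_components = n_components,
                                     threshold = threshold, top_m = top_m))
}

#' Characteristic wavelengths from second-derivative extrema
#'
#' Applies the same interior peak/valley rule to the mean second-derivative
#' spectrum (grand mean by default, or per-class means unioned).
#'
#' @param ds_d2 a [spectral_dataset()] holding second-derivative spectra
#'   (`deriv == 2`, as produced by [savitzky_golay()]).
#' @param threshold minimum absolute derivative value (default 0).
#' @param per_class union extrema of per-class mean curves instead of the
#'   grand mean (default `FALSE`).
#' @param top_m optional cap on the number of selected wavelengths.
#' @return A [selected_wavelengths()] with source `"second_derivative"`.
#' @export
pick_derivative_extrema <- function(ds_d2, threshold = 0, per_class = FALSE,
                                    top_m = NULL) {
  stopifnot(inherits(ds_d2, "spectral_dataset"))
  if (ds_d2$deriv != 2L)
    stop_bad_arg("input must carry second-derivative spectra (deriv == 2)")
  curves <- if (per_class && !is.null(ds_d2$y)) {
    lapply(sort(unique(ds_d2$y)), function(cl)
      colMeans(ds_d2$x[ds_d2$y == cl, , drop = FALSE]))
  } else list(colMeans(ds_d2$x))
  best <- numeric(0)
  for (v in curves) {
    ext <- local_extrema(v)
    ext <- ext[abs(v[ext]) >= threshold]
    for (i in ext) {
      key <- as.character(i)
      best[key] <- max(best[key], abs(v[i]), na.rm = TRUE)
    }
  }
  idx <- as.integer(names(best))
  if (!is.null(top_m) && length(idx) > top_m)
    idx <- idx[rank(-best, ties.method = "first") <= top_m]
  selected_wavelengths(idx, ds_d2$axis, "second_derivative",
                       params = list(threshold = threshold,
                                     per_class = per_class, top_m = top_m))
}

#' Restrict a dataset to selected wavelengths
#'
#' @param ds a [spectral_dataset()] on the axis the selection refers to.
#' @param sel a [selected_wavelengths()].
#' @return A [spectral_dataset()] with only the selected bands.
#' @export
apply_selection <- function(ds, sel) {
  stopifnot(inherits(ds, "spectral_dataset"),
            inherits(sel, "selected_wavelengths"))
  idx <- sel$band_indices
  if (length(idx) == 0L) stop_bad_arg("empty wavelength selection")
  if (max(idx) > n_bands(ds)) stop_bad_arg("selection indices exceed the axis")
  if (max(abs(as.numeric(ds$axis)[idx] - sel$wavelengths_nm)) > 1e-8)
    stop_bad_arg("selection was made on a different wavelength axis")
  spectral_dataset(ds$x[, idx, drop = FALSE],
                   wavelength_axis(as.numeric(ds$axis)[idx]),
                   y = ds$y, ids = ds$ids, deriv = ds$deriv)
}
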