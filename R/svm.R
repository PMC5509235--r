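#' RBF-kernel support vector machine with (c, g) grid search
#'
#' One-vs-one soft-margin SVM with a Gaussian kernel (delegating the solver
#' to \pkg{e1071}/libsvm; `g` is the libsvm `gamma`). The penalty `c` and
#' kernel parameter `g` are chosen from a grid of powers of two by k-fold
#' cross-validation accuracy within the calibration set; ties go to the
#' earliest grid point (c-major order).
#'
#' @param ds_cal calibration [spectral_dataset()] with class labels.
#' @param c_grid,g_grid positive candidate values; defaults are powers of
#'   two spanning c in 2^-5..2^10 and g in 2^-10..2^5.
#' @param folds cross-validation folds (default 5).
#' @param seed seed for the cross-validation partition.
#' @param standardize z-score features by calibration statistics (default).
#' @return An object of class `svm_fit` with the fitted model, `c`, `g` and
#'   the grid of cross-validation accuracies.
#' @export
train_svm <- function(ds_cal, c_grid = 2^seq(-5, 10, by = 5),
                      g_grid = 2^seq(-10, 5, by = 5), folds = 5L, seed = 1L,
                      standardize = TRUE) {
  stopifnot(inherits(ds_cal, "spectral_dataset"))
  y <- check_labels(ds_cal, "train_svm")
  if (any(c_grid <= 0) || any(g_grid <= 0))
    stop_bad_arg("c and g must be positive")
  scaler <- if (standardize) fit_scaler(ds_cal$x) else NULL
  x <- apply_scaler(ds_cal$x, scaler)
  yf <- factor(y)
  acc <- matrix(NA_real_, length(c_grid), length(g_grid),
                dimnames = list(format(c_grid), format(g_grid)))
  single <- length(c_grid) == 1L && length(g_grid) == 1L
  for (i in seq_along(c_grid)) for (j in seq_along(g_grid)) {
    if (single) { acc[i, j] <- 100; next }
    acc[i, j] <- with_seed(seed,
      e1071::svm(x, yf, kernel = "radial", cost = c_grid[i],
                 gamma = g_grid[j], cross = folds, scale = FALSE)$tot.accuracy)
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  fit <- e1071::svm(x, yf, kernel = "radial", cost = c_grid[best[1]],
                    gamma = g_grid[best[2]], scale = FALSE)
  structure(list(model = fit, c = c_grid[best[1]], g = g_grid[best[2]],
                 cv_accuracy = acc, levels = sort(unique(y)),
                 scaler = scaler, axis = ds_cal$axis),
            class = "svm_fit")
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  x <- model_features(object, newdata)
  as.integer(as.character(predict(object$model, x)))
}

#' @export
print.svm_fit <- function(x, ...) {
  cat(sprintf("<svm_fit> RBF kernel, c = %g, g = %g, %d classes\n",
              x$c, x$g, length(x$levels)))
  invisible(x)
}
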