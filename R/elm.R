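#' Extreme learning machine classifier
#'
#' Single-hidden-layer network with random fixed input weights and
#' least-squares-solved output weights: input weights and biases are drawn
#' uniformly in \[-1, 1\] from the seeded generator, the hidden activation
#' matrix `H` (n x h, logistic sigmoid by default) is formed, and the output
#' weights are `pinv(H) %*% T` for one-hot targets `T`. Prediction is the
#' argmax over the class outputs.
#'
#' @param ds_cal calibration [spectral_dataset()] with class labels.
#' @param h hidden-node count.
#' @param activation `"sigmoid"` (default) or `"tanh"`.
#' @param seed integer seed for the random input layer.
#' @param standardize z-score features by calibration statistics (default).
#' @return An object of class `elm_model`.
#' @export
train_elm <- function(ds_cal, h, activation = c("sigmoid", "tanh"), seed = 1L,
                      standardize = TRUE) {
  stopifnot(inherits(ds_cal, "spectral_dataset"))
  y <- check_labels(ds_cal, "train_elm")
  activation <- match.arg(activation)
  h <- as.integer(h)
  if (h < 1L) stop_bad_arg("h must be >= 1")
  scaler <- if (standardize) fit_scaler(ds_cal$x) else NULL
  x <- apply_scaler(ds_cal$x, scaler)
  d <- ncol(x)
  levels <- sort(unique(y))
  with_seed(seed, {
    w <- matrix(runif(h * d, -1, 1), h, d)
    b <- runif(h, -1, 1)
    hid <- elm_hidden(x, w, b, activation)
    if (max(abs(sweep(hid, 2, hid[1, ]))) < 1e-10)
      stop_bad_arg("degenerate hidden layer: all activation rows identical")
    beta <- MASS::ginv(hid) %*% one_hot(y, levels)
    structure(list(input_weights = w, biases = b, output_weights = beta,
                   activation = activation, h = h, seed = as.integer(seed),
                   levels = levels, scaler = scaler, axis = ds_cal$axis),
              class = "elm_model")
  })
}

elm_hidden <- function(x, w, b, activation) {
  z <- sweep(x %*% t(w), 2, b, "+")
  switch(activation,
         sigmoid = 1 / (1 + exp(-z)),
         tanh = tanh(z))
}

#' @export
predict.elm_model <- function(object, newdata, ...) {
  x <- model_features(object, newdata)
  hid <- elm_hidden(x, object$input_weights, object$biases, object$activation)
  object$levels[max.col(hid %*% object$output_weights, ties.method = "first")]
}

#' @export
print.elm_model <- function(x, ...) {
  cat(sprintf("<elm_model> h = %d hidden nodes (%s), %d classes, seed %d\n",
              x$h, x$activation, length(x$levels), x$seed))
  invisible(x)
}

#' Hidden-node search for the extreme learning machine
#'
#' Scans the hidden-node count over `h_range` (default 1-150 in steps of 1)
#' and returns the smallest `h` whose training misclassification error
#' attains the minimum over the scan. A warning is raised when the optimum
#' sits on the scan ceiling, since the true optimum may lie beyond it; the
#' ceiling is configurable.
#'
#' @param ds_cal calibration [spectral_dataset()] with class labels.
#' @param h_range integer vector of hidden-node counts to scan.
#' @param seed seed used for every candidate's random input layer.
#' @param ... passed to [train_elm()].
#' @return List with `h` (chosen count), `model` (the refitted
#'   [train_elm()] model) and `train_error` (per-candidate error rates).
#' @export
search_elm <- function(ds_cal, h_range = 1:150, seed = 1L, ...) {
  y <- check_labels(ds_cal, "search_elm")
  h_range <- sort(unique(as.integer(h_range)))
  if (length(h_range) == 0L) stop_bad_arg("empty h_range")
  err <- vapply(h_range, function(h) {
    m <- train_elm(ds_cal, h, seed = seed, ...)
    mean(predict(m, ds_cal) != y)
  }, numeric(1))
  best <- h_range[which.min(err)]   # which.min: first (smallest h) minimizer
  if (best == max(h_range) && length(h_range) > 1L)
    warning("ELM search optimum sits at the scan ceiling (h = ", best,
            "); consider raising the ceiling")
  list(h = best, model = train_elm(ds_cal, best, seed = seed, ...),
       train_error = stats::setNames(err, h_range))
}
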