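# Shared helpers for the discriminant models: feature standardization by
# calibration statistics and one-hot class targets.

fit_scaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  if (is.null(scaler)) return(x)
  sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

one_hot <- function(y, levels) {
  t_mat <- matrix(0, length(y), length(levels))
  t_mat[cbind(seq_along(y), match(y, levels))] <- 1
  t_mat
}

check_labels <- function(ds, what) {
  if (is.null(ds$y)) stop_bad_arg(what, " needs class labels")
  ds$y
}

model_features <- function(model, ds) {
  if (!isTRUE(all.equal(as.numeric(model$axis), as.numeric(ds$axis))))
    stop_bad_arg("dataset axis does not match the axis the model was trained on")
  apply_scaler(ds$x, model$scaler)
}

seeded_folds <- function(n, folds, seed) {
  with_seed(seed, sample(rep_len(seq_len(folds), n)))
}
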