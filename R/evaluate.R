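#' Evaluation report for one model on one set
#'
#' Builds the confusion matrix (rows = true class), per-class accuracies and
#' the macro-mean accuracy — the unweighted average of the per-class
#' accuracies, the "Mean" figure of the standard results tables.
#'
#' @param confusion square count matrix, rows = true class, columns =
#'   predicted class, dimnames = class labels.
#' @param set_name `"calibration"` or `"prediction"`.
#' @return An object of class `eval_report` with `confusion`,
#'   `per_class_accuracy` (percent) and `mean_accuracy` (percent).
#' @export
eval_report <- function(confusion, set_name = c("calibration", "prediction")) {
  set_name <- match.arg(set_name)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop_bad_arg("confusion matrix must be square")
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop_bad_arg("confusion matrix must hold non-negative counts")
  if (is.null(rownames(confusion)))
    dimnames(confusion) <- list(seq_len(nrow(confusion)),
                                seq_len(ncol(confusion)))
  rs <- rowSums(confusion)
  if (any(rs == 0)) stop_bad_arg("every true class needs at least one sample")
  per_class <- 100 * diag(confusion) / rs
  names(per_class) <- rownames(confusion)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 mean_accuracy = mean(per_class),
                 set_name = set_name),
            class = "eval_report")
}

#' Evaluate a discriminant model on a labeled dataset
#'
#' @param model a fitted `elm_model`, `rbf_net` or `svm_fit`.
#' @param ds a labeled [spectral_dataset()] on the model's axis.
#' @param set_name `"calibration"` or `"prediction"`.
#' @return An [eval_report()].
#' @export
evaluate <- function(model, ds, set_name = c("calibration", "prediction")) {
  stopifnot(inherits(ds, "spectral_dataset"))
  y <- check_labels(ds, "evaluate")
  levels <- model$levels
  if (is.null(levels)) stop_bad_arg("model carries no class levels")
  if (!all(y %in% levels))
    stop_bad_arg("dataset contains class labels unseen at training: ",
                 paste(setdiff(y, levels), collapse = ", "))
  pred <- predict(model, ds)
  confusion <- table(factor(y, levels = levels),
                     factor(pred, levels = levels))
  eval_report(unclass(as.matrix(confusion)), set_name = match.arg(set_name))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s set\n", x$set_name))
  cat("  per-class accuracy (%):",
      paste(sprintf("%s=%.2f", names(x$per_class_accuracy),
                    x$per_class_accuracy), collapse = "  "), "\n")
  cat(sprintf("  macro-mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}
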