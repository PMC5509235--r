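#' Kennard-Stone calibration/prediction split
#'
#' Classic deterministic max-min procedure: seed the calibration set with the
#' two mutually farthest samples (Euclidean distance on the preprocessed
#' spectra), then repeatedly add the sample whose minimum distance to the
#' already-chosen set is largest, until the calibration quota is met. With
#' `per_class = TRUE` (the default) the procedure runs within each class, so
#' a 2:1 split of 300 samples per origin yields 200 calibration samples per
#' origin. Ties are broken toward the lexicographically smallest sample id,
#' making the split invariant to row order.
#'
#' @param ds a [spectral_dataset()] with class labels when `per_class`.
#' @param ratio calibration:prediction ratio (default 2, i.e. 2:1).
#' @param per_class stratify by class label (default `TRUE`).
#' @return An object of class `split_result` with `calibration_ids`,
#'   `prediction_ids` (disjoint, union = all ids) and `ratio`.
#' @export
kennard_stone_split <- function(ds, ratio = 2, per_class = TRUE) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (ratio <= 0) stop_bad_arg("ratio must be positive")
  strata <- if (per_class) {
    if (is.null(ds$y)) stop_bad_arg("per-class split needs class labels")
    split(seq_len(n_samples(ds)), ds$y)
  } else list(seq_len(n_samples(ds)))
  cal <- character(0)
  for (idx in strata) {
    n <- length(idx)
    quota <- round(n * ratio / (ratio + 1))
    if (n < 2L || quota < 2L)
      stop_bad_arg("each stratum needs at least 2 calibration samples; ",
                   "got quota ", quota, " of ", n)
    cal <- c(cal, ks_select(ds$x[idx, , drop = FALSE], ds$ids[idx], quota))
  }
  cal <- ds$ids[ds$ids %in% cal]   # restore dataset order
  structure(list(calibration_ids = cal,
                 prediction_ids = setdiff(ds$ids, cal),
                 ratio = ratio),
            class = "split_result")
}

# greedy max-min selection of `quota` rows; ids break all ties
ks_select <- function(x, ids, quota) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  pref <- order(ids)            # tie-break preference: smaller id first
  rank_id <- integer(n); rank_id[pref] <- seq_len(n)
  # seed pair: maximum distance; among ties the pair whose sorted id ranks
  # are smallest
  best <- c(NA_integer_, NA_integer_); best_d <- -Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dij <- d[i, j]
    if (dij > best_d + 1e-12) {
      best <- c(i, j); best_d <- dij
    } else if (abs(dij - best_d) <= 1e-12) {
      cand <- sort(rank_id[c(i, j)]); cur <- sort(rank_id[best])
      if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
        best <- c(i, j)
    }
  }
  sel <- best[order(rank_id[best])]
  if (quota >= n) return(ids)
  min_d <- pmin(d[, sel[1]], d[, sel[2]])
  while (length(sel) < quota) {
    min_d[sel] <- -Inf
    cand <- which(min_d >= max(min_d) - 1e-12)
    nxt <- cand[which.min(rank_id[cand])]
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, d[, nxt])
  }
  ids[sel]
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction (ratio %g:1)\n",
              length(x$calibration_ids), length(x$prediction_ids), x$ratio))
  invisible(x)
}
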