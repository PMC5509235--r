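# Independent oracles used across the suite. These deliberately use naive
# algorithms (BFS flood fill, exhaustive scans, dense grids, direct
# eigendecompositions) so they share no code with the implementation.

# 4-connected components of a logical matrix by BFS flood fill
flood_fill_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(mask) && q[2] >= 1 &&
            q[2] <= ncol(mask) && mask[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# greedy Kennard-Stone oracle: plain transcription of the max-min rule,
# breaking ties toward the smallest row index (rows assumed id-sorted)
ks_oracle <- function(x, quota) {
  d <- as.matrix(dist(x))
  n <- nrow(x)
  pair <- which(d == max(d), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- sort(pair)
  while (length(sel) < quota) {
    rest <- setdiff(seq_len(n), sel)
    mind <- sapply(rest, function(j) min(d[j, sel]))
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}

# exhaustive interior local-extremum scan (no plateau handling; callers use
# tie-free inputs)
extrema_scan <- function(v) {
  idx <- integer()
  for (i in 2:(length(v) - 1)) {
    if ((v[i] > v[i - 1] && v[i] > v[i + 1]) ||
        (v[i] < v[i - 1] && v[i] < v[i + 1])) idx <- c(idx, i)
  }
  idx
}

# covariance eigendecomposition oracle for PCA
cov_eigen_oracle <- function(x, k) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(cov(xc), symmetric = TRUE)
  list(values = eig$values[seq_len(k)],
       vectors = eig$vectors[, seq_len(k), drop = FALSE])
}

# small labeled toy dataset of well-separated Gaussian blobs
toy_blobs <- function(n_per_class = 15, d = 6, sep = 4, classes = 4,
                      seed = 42, sd = 0.5) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(classes), function(k) {
    mu <- rep(0, d); mu[(k - 1) %% d + 1] <- sep
    matrix(rnorm(n_per_class * d, sd = sd), n_per_class, d) +
      matrix(mu, n_per_class, d, byrow = TRUE)
  }))
  spectral_dataset(x, wavelength_axis(seq(1000, 1000 + 10 * (d - 1), by = 10)),
                   y = rep(seq_len(classes), each = n_per_class))
}

small_spec <- function(n_rows = 60, n_cols = 80, n_bands = 40)
  acquisition_spec(n_rows, n_cols, n_bands)
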