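test_that("stratified 2:1 Kennard-Stone yields 200 calibration samples per class", {
  ds <- make_sample_library(default_origin_models(), n_per_class = 300,
                            axis = default_wavelength_axis(40), seed = 1)
  sp <- kennard_stone_split(ds, ratio = 2, per_class = TRUE)
  cal <- subset_samples(ds, sp$calibration_ids)
  expect_equal(as.vector(table(cal$y)), rep(200L, 4))
  expect_length(sp$prediction_ids, 400)
  expect_length(intersect(sp$calibration_ids, sp$prediction_ids), 0)
  expect_setequal(c(sp$calibration_ids, sp$prediction_ids), ds$ids)
})

test_that("Kennard-Stone selects the far pair first and matches the greedy oracle", {
  set.seed(12)
  for (rep_i in 1:5) {
    x <- matrix(runif(16), 8, 2)
    ds <- spectral_dataset(x, wavelength_axis(c(1000, 1010)))
    sp <- kennard_stone_split(ds, ratio = 1, per_class = FALSE)  # quota 4
    oracle_sel <- ks_oracle(x, 4)
    expect_setequal(sp$calibration_ids, as.character(oracle_sel))
  }
  # two points, quota 2: both selected
  two <- spectral_dataset(matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE),
                          wavelength_axis(c(1000, 1010)))
  sp2 <- kennard_stone_split(two, ratio = 9, per_class = FALSE)
  expect_setequal(sp2$calibration_ids, c("1", "2"))
  expect_error(kennard_stone_split(two, ratio = 0.1, per_class = FALSE),
               "at least 2")
})

test_that("Kennard-Stone is invariant to row permutation", {
  set.seed(3)
  x <- matrix(rnorm(60), 20, 3)
  ids <- sprintf("s%02d", 1:20)
  ds <- spectral_dataset(x, wavelength_axis(c(1000, 1010, 1020)), ids = ids)
  perm <- sample(20)
  dsp <- spectral_dataset(x[perm, ], wavelength_axis(c(1000, 1010, 1020)),
                          ids = ids[perm])
  s1 <- kennard_stone_split(ds, 2, per_class = FALSE)
  s2 <- kennard_stone_split(dsp, 2, per_class = FALSE)
  expect_setequal(s1$calibration_ids, s2$calibration_ids)
})

test_that("ELM interpolates exactly at h = n and is seed-reproducible", {
  ds <- toy_blobs(n_per_class = 5, classes = 3, seed = 21)
  m <- train_elm(ds, h = n_samples(ds), seed = 4)
  expect_equal(evaluate(m, ds, "calibration")$mean_accuracy, 100)
  m2 <- train_elm(ds, h = n_samples(ds), seed = 4)
  expect_identical(m$input_weights, m2$input_weights)
  expect_identical(predict(m, ds), predict(m2, ds))
  m3 <- train_elm(ds, h = n_samples(ds), seed = 5)
  expect_false(identical(m3$input_weights, m$input_weights))
})

test_that("ELM recovers well-separated classes across seeds", {
  accs <- vapply(1:20, function(s) {
    tr <- make_sample_library(default_origin_models(separation = 6),
                              n_per_class = 25,
                              axis = default_wavelength_axis(50),
                              seed = 100 + s)
    te <- make_sample_library(default_origin_models(separation = 6),
                              n_per_class = 10,
                              axis = default_wavelength_axis(50),
                              seed = 300 + s)
    m <- train_elm(tr, h = 30, seed = s)
    evaluate(m, te, "prediction")$mean_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 95)
  expect_lt(var(accs) / 100, 2)  # stable across seeds (percentage points)
})

test_that("ELM hidden-node search returns the first full-scan minimizer", {
  ds <- toy_blobs(n_per_class = 8, classes = 3, sep = 6, seed = 31)
  res <- search_elm(ds, h_range = 1:12, seed = 2)
  full_scan <- vapply(1:12, function(h) {
    m <- train_elm(ds, h, seed = 2)
    mean(predict(m, ds) != ds$y)
  }, numeric(1))
  expect_equal(res$h, which(full_scan == min(full_scan))[1])
  expect_equal(unname(res$train_error), full_scan)
  # a scan of size 1 returns that h
  expect_equal(search_elm(ds, h_range = 7, seed = 2)$h, 7)
  # zero training error reachable by a small network on separable data
  expect_lte(res$h, 5)
})

test_that("exact-design RBF net hits 100% training accuracy in the local limit", {
  ds <- toy_blobs(n_per_class = 6, classes = 3, seed = 41)
  suppressMessages({
    m <- train_rbf_net(ds, spread_grid = 0.01)
  })
  expect_equal(evaluate(m, ds, "calibration")$mean_accuracy, 100)
  one_class <- spectral_dataset(ds$x[1:6, ], ds$axis, y = rep(1, 6))
  suppressMessages({
    m1 <- train_rbf_net(one_class, spread_grid = c(0.5, 5))
  })
  expect_equal(evaluate(m1, one_class, "calibration")$mean_accuracy, 100)
  expect_error(train_rbf_net(ds, spread_grid = numeric()), "positive")
})

test_that("RBF spread selection tracks an exhaustive grid oracle", {
  ds <- toy_blobs(n_per_class = 20, d = 2, classes = 4, sep = 3, seed = 51)
  grid <- c(0.2, 0.5, 1, 2, 5, 10)
  m <- train_rbf_net(ds, spread_grid = grid, folds = 5, seed = 7)
  # oracle: recompute every grid point's CV accuracy independently
  fold_id <- berrytrace:::seeded_folds(n_samples(ds), 5, 7)
  oracle_acc <- vapply(grid, function(s) {
    hits <- 0
    for (f in 1:5) {
      tr <- subset_samples(ds, which(fold_id != f))
      te <- subset_samples(ds, which(fold_id == f))
      suppressMessages(mf <- train_rbf_net(tr, spread_grid = s))
      hits <- hits + sum(predict(mf, te) == te$y)
    }
    100 * hits / n_samples(ds)
  }, numeric(1))
  chosen_cv <- 100 * max(m$cv_accuracy)
  expect_lte(abs(chosen_cv - max(oracle_acc)), 2)
})

test_that("SVM grid search finds separating configurations", {
  ds <- toy_blobs(n_per_class = 10, d = 3, classes = 2, sep = 5, seed = 61)
  m <- train_svm(ds, c_grid = c(1, 100), g_grid = c(0.01, 1), folds = 3)
  expect_equal(evaluate(m, ds, "calibration")$mean_accuracy, 100)
  single <- train_svm(ds, c_grid = 8, g_grid = 0.5)
  expect_equal(single$c, 8)
  expect_equal(single$g, 0.5)
  expect_error(train_svm(ds, c_grid = -1, g_grid = 1), "positive")
})

test_that("RBF-kernel SVM solves XOR where a linear kernel cannot", {
  set.seed(71)
  n <- 40
  x <- matrix(runif(2 * n, -1, 1), n, 2)
  y <- ifelse(x[, 1] * x[, 2] > 0, 1L, 2L)
  ds <- spectral_dataset(x + rnorm(2 * n, 0, 0.02),
                         wavelength_axis(c(1000, 1010)), y = y)
  m <- train_svm(ds, c_grid = c(1, 10, 100), g_grid = c(0.5, 2, 8), folds = 5)
  rbf_acc <- evaluate(m, ds, "calibration")$mean_accuracy
  expect_gt(rbf_acc, 90)
  # linear-kernel control run, brute force over costs
  lin_acc <- max(vapply(c(0.1, 1, 10, 100), function(cc) {
    fit <- e1071::svm(ds$x, factor(ds$y), kernel = "linear", cost = cc,
                      scale = FALSE)
    100 * mean(predict(fit, ds$x) == ds$y)
  }, numeric(1)))
  expect_lt(lin_acc, rbf_acc)
  expect_lt(lin_acc, 75)
})

test_that("macro-mean accuracy reproduces the published arithmetic", {
  # per-class accuracies realized as confusion rows of 100 (or 200) samples
  conf_from_acc <- function(acc, n_per_class) {
    k <- length(acc)
    conf <- matrix(0, k, k)
    for (i in seq_len(k)) {
      hits <- round(acc[i] / 100 * n_per_class)
      conf[i, i] <- hits
      conf[i, if (i == k) 1 else i + 1] <- n_per_class - hits
    }
    conf
  }
  svm_cal <- eval_report(conf_from_acc(c(96, 88, 86, 94), 100), "calibration")
  expect_equal(svm_cal$mean_accuracy, 91.00)
  elm_prd <- eval_report(conf_from_acc(c(97, 86, 83, 99), 100), "prediction")
  expect_equal(elm_prd$mean_accuracy, 91.25)
  rows <- list(c(99, 83, 76, 95, 88.25), c(100, 92.5, 96, 99.5, 97.00),
               c(98, 87, 79, 97, 90.25), c(100, 92.5, 93.5, 99, 96.25))
  for (r in rows) {
    rep_i <- eval_report(conf_from_acc(r[1:4], 200), "calibration")
    expect_equal(rep_i$mean_accuracy, r[5])
  }
})

test_that("evaluation validates labels and reports perfect prediction as 100", {
  ds <- toy_blobs(n_per_class = 5, classes = 3, seed = 81)
  m <- train_elm(ds, h = 15, seed = 1)
  rep0 <- evaluate(m, ds, "calibration")
  expect_equal(sum(rep0$confusion), n_samples(ds))
  expect_equal(unname(rowSums(rep0$confusion)), rep(5, 3))
  perfect <- eval_report(diag(4) * 25, "prediction")
  expect_equal(perfect$mean_accuracy, 100)
  bad <- spectral_dataset(ds$x, ds$axis, y = rep(c(1, 9), length.out = 15))
  expect_error(evaluate(m, bad, "prediction"), "unseen")
})

test_that("classifiers separate strong classes and hit chance under the null", {
  ax <- default_wavelength_axis(40)
  strong <- make_sample_library(default_origin_models(separation = 6),
                                n_per_class = 45, axis = ax, seed = 5)
  sp <- kennard_stone_split(strong, 2)
  cal <- subset_samples(strong, sp$calibration_ids)
  prd <- subset_samples(strong, sp$prediction_ids)
  suppressMessages({
    fits <- list(svm = train_svm(cal, c_grid = c(1, 100), g_grid = c(0.01, 1),
                                 folds = 3),
                 rbf = train_rbf_net(cal, spread_grid = c(1, 5, 25), folds = 3),
                 elm = train_elm(cal, h = 40, seed = 1))
  })
  for (m in fits)
    expect_gte(evaluate(m, prd, "prediction")$mean_accuracy, 99)

  # chance-level null on independently drawn test data: evaluating on the
  # Kennard-Stone prediction set would inflate memorizing classifiers, since
  # within-class KS leaves each class's held-out points near that class's own
  # calibration points even when the classes are identical
  null_accs <- sapply(1:8, function(s) {
    cal0 <- make_sample_library(default_origin_models(separation = 0),
                                n_per_class = 40, axis = ax, seed = 500 + s)
    prd0 <- make_sample_library(default_origin_models(separation = 0),
                                n_per_class = 20, axis = ax, seed = 700 + s)
    suppressMessages(suppressWarnings({
      c(evaluate(train_svm(cal0, c_grid = c(1, 100), g_grid = c(0.01, 1),
                           folds = 3), prd0, "prediction")$mean_accuracy,
        evaluate(train_rbf_net(cal0, spread_grid = c(1, 5, 25), folds = 3),
                 prd0, "prediction")$mean_accuracy,
        evaluate(train_elm(cal0, h = 40, seed = 1), prd0,
                 "prediction")$mean_accuracy)
    }))
  })
  for (i in 1:3) expect_lt(abs(mean(null_accs[i, ]) - 25), 5)
})
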