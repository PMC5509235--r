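#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run with defaults encoding the
#' reference workflow: 256-band 874-1734 nm acquisition, four origin classes
#' of 300 samples, truncation to 972-1609 nm, moving-average window 5,
#' Savitzky-Golay window 9 / order 3, five PCA components for selection,
#' stratified 2:1 Kennard-Stone split, ELM hidden-node scan 1-150, the
#' NN-RBF spread ladder over 0.1-1 and 1-100, and an SVM grid of powers of
#' two spanning c in 2^-5..2^10 and g in 2^-10..2^5.
#'
#' @param seed master seed for every stochastic stage.
#' @param acquisition an [acquisition_spec()].
#' @param separation,noise_sd,scatter_sd synthetic-scene class contrast and
#'   noise levels (see [default_origin_models()]).
#' @param n_objects_per_class objects per class in rendered scenes.
#' @param radius_range ellipse semi-axis range (px) for rendered berries.
#' @param n_per_class samples per class in the object-wise library.
#' @param truncate_nm length-2 retained wavelength window.
#' @param ma_window moving-average window (bands).
#' @param sg_window,sg_polyorder Savitzky-Golay settings for derivatives.
#' @param n_components loading vectors scanned for selection.
#' @param loading_threshold,loading_top_m PCA-loadings selection controls.
#' @param d2_threshold second-derivative selection threshold.
#' @param split_ratio calibration:prediction ratio.
#' @param mask_threshold background mask reflectance threshold.
#' @param min_object_px minimum object size in pixels.
#' @param elm_h_range,rbf_spread_grid,svm_c_grid,svm_g_grid model searches.
#' @param cv_folds folds for the model-selection cross-validations.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            acquisition = acquisition_spec(),
                            separation = 1, noise_sd = 0.01, scatter_sd = 0.02,
                            n_objects_per_class = 3L,
                            radius_range = c(8, 14),
                            n_per_class = 300L,
                            truncate_nm = c(972, 1609),
                            ma_window = 5L,
                            sg_window = 9L, sg_polyorder = 3L,
                            n_components = 5L,
                            loading_threshold = 0, loading_top_m = 20L,
                            d2_threshold = 0,
                            split_ratio = 2,
                            mask_threshold = 0.15,
                            min_object_px = 20L,
                            elm_h_range = 1:150,
                            rbf_spread_grid = c(seq(0.1, 1, by = 0.1),
                                                c(2, 5, 10, 25, 50, 100)),
                            svm_c_grid = 2^seq(-5, 10, by = 5),
                            svm_g_grid = 2^seq(-10, 5, by = 5),
                            cv_folds = 5L) {
  stopifnot(inherits(acquisition, "acquisition_spec"))
  if (length(truncate_nm) != 2L || truncate_nm[1] >= truncate_nm[2])
    stop_bad_arg("truncate_nm must be an increasing (lo, hi) pair")
  if (n_per_class < 3L) stop_bad_arg("n_per_class must be at least 3")
  cfg <- list(seed = as.integer(seed), acquisition = acquisition,
              separation = separation, noise_sd = noise_sd,
              scatter_sd = scatter_sd,
              n_objects_per_class = as.integer(n_objects_per_class),
              radius_range = radius_range,
              n_per_class = as.integer(n_per_class),
              truncate_nm = truncate_nm, ma_window = as.integer(ma_window),
              sg_window = as.integer(sg_window),
              sg_polyorder = as.integer(sg_polyorder),
              n_components = as.integer(n_components),
              loading_threshold = loading_threshold,
              loading_top_m = loading_top_m,
              d2_threshold = d2_threshold, split_ratio = split_ratio,
              mask_threshold = mask_threshold,
              min_object_px = as.integer(min_object_px),
              elm_h_range = elm_h_range,
              rbf_spread_grid = rbf_spread_grid,
              svm_c_grid = svm_c_grid, svm_g_grid = svm_g_grid,
              cv_folds = as.integer(cv_folds))
  class(cfg) <- "pipeline_config"
  cfg
}

write_config_snapshot <- function(cfg, outdir) {
  txt <- utils::capture.output(utils::str(cfg, give.head = FALSE))
  writeLines(c("# resolved pipeline configuration", txt),
             file.path(outdir, "config.txt"))
}

#' Pixel-wise analysis: PCA score images of a scene
#'
#' Renders (or takes) a scene, calibrates it, masks the background, segments
#' the berries, extracts every foreground pixel's spectrum and fits a 5-PC
#' PCA. Returns the score images (score rasters with `NA` background), the
#' 2-D scatter data for (PC3, PC4) and (PC5, PC4), and the cumulative
#' explained variance of the five components.
#'
#' @param cfg a [pipeline_config()].
#' @param scene optional scene list (as from [render_scene()]); rendered
#'   from the config when `NULL`.
#' @param outdir optional directory for CSV/PNG outputs.
#' @return List with `pca`, `score_images`, `scatter`, `cumulative_variance`,
#'   `pixels`, `segmentation` and `scene`.
#' @export
run_pixelwise <- function(cfg = pipeline_config(), scene = NULL,
                          outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(scene))
    scene <- render_scene(cfg$acquisition,
                          default_origin_models(cfg$separation, cfg$noise_sd,
                                                cfg$scatter_sd),
                          n_objects_per_class = cfg$n_objects_per_class,
                          seed = cfg$seed, radius_range = cfg$radius_range)
  refl <- calibrate_cube(scene$raw, scene$refs)
  mask <- mask_background(refl, threshold = cfg$mask_threshold)
  seg <- segment_objects(mask, min_size = cfg$min_object_px)
  class_map <- NULL
  if (!is.null(scene$truth)) {
    # majority-overlap vote against the truth labels
    class_map <- vapply(seq_len(nrow(seg$objects)), function(i) {
      tl <- scene$truth$label_image[seg$labels == i]
      tl <- tl[tl > 0]
      if (length(tl) == 0) return(NA_integer_)
      obj <- as.integer(names(sort(table(tl), decreasing = TRUE))[1])
      scene$truth$object_table$class_id[
        scene$truth$object_table$object_id == obj]
    }, integer(1))
    names(class_map) <- seg$objects$object_id
  }
  px <- extract_pixel_spectra(refl, seg$labels, class_map)
  pds <- spectral_dataset(px$x, px$axis,
                          y = if (!anyNA(px$info$class_id)) px$info$class_id,
                          ids = sprintf("px%06d", seq_len(nrow(px$x))))
  k <- min(5L, n_samples(pds) - 1L, n_bands(pds))
  pca <- fit_pca(pds, k = k)
  dims <- dim(refl$values)[1:2]
  score_images <- lapply(seq_len(k), function(j) {
    img <- matrix(NA_real_, dims[1], dims[2])
    img[cbind(px$info$row, px$info$col)] <- pca$scores[, j]
    img
  })
  names(score_images) <- paste0("PC", seq_len(k))
  scatter <- data.frame(px$info[, c("row", "col", "object_id", "class_id")],
                        pca$scores[, seq_len(k), drop = FALSE])
  out <- list(pca = pca, score_images = score_images, scatter = scatter,
              cumulative_variance = 100 * sum(pca$explained_ratio),
              pixels = px, segmentation = seg, scene = scene)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_config_snapshot(cfg, outdir)
    write.csv(scatter, file.path(outdir, "pixel_scores.csv"),
              row.names = FALSE)
    write.csv(data.frame(component = seq_len(k),
                         explained_pct = 100 * pca$explained_ratio),
              file.path(outdir, "explained_variance.csv"), row.names = FALSE)
    for (j in seq_len(k))
      save_score_image(score_images[[j]],
                       file.path(outdir, sprintf("score_image_PC%d.png", j)),
                       sprintf("PC%d scores", j))
  }
  out
}

#' Render a score image to PNG
#'
#' Fixed diverging palette, per-image symmetric min/max scaling, background
#' (`NA`) in grey.
#'
#' @param img score matrix with `NA` background.
#' @param path output PNG path.
#' @param title plot title.
#' @return `path`, invisibly.
#' @export
save_score_image <- function(img, path, title = "scores") {
  grDevices::png(path, width = 640, height = 520)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "Blue-Red 3")
  lim <- max(abs(img), na.rm = TRUE)
  graphics::par(mar = c(2, 2, 3, 1))
  graphics::image(t(img[nrow(img):1, , drop = FALSE]), col = pal,
                  zlim = c(-lim, lim), axes = FALSE, main = title)
  invisible(path)
}

#' Object-wise analysis: three models on three feature sets
#'
#' Builds (or takes) the object-wise sample library, truncates and smooths
#' it, makes the stratified Kennard-Stone split, derives the PCA-loadings
#' and second-derivative wavelength selections from the calibration set,
#' then trains and evaluates SVM, NN-RBF and ELM on the full spectra and on
#' both selections — nine model/feature-set combinations, each with a
#' calibration and a prediction report.
#'
#' @param cfg a [pipeline_config()].
#' @param ds optional [spectral_dataset()] on the full instrument axis;
#'   generated from the config when `NULL`.
#' @param outdir optional directory for CSV outputs.
#' @return List with `results` (nested: feature set, then model, each with
#'   `calibration`/`prediction` [eval_report()]s and chosen parameters),
#'   `selections`, `split` and the preprocessed `data`.
#' @export
run_objectwise <- function(cfg = pipeline_config(), ds = NULL, outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(ds))
    ds <- make_sample_library(
      default_origin_models(cfg$separation, cfg$noise_sd, cfg$scatter_sd),
      n_per_class = cfg$n_per_class, axis = spec_axis(cfg$acquisition),
      seed = cfg$seed)
  pre <- moving_average(
    truncate_band_range(ds, cfg$truncate_nm[1], cfg$truncate_nm[2]),
    cfg$ma_window)
  split <- kennard_stone_split(pre, ratio = cfg$split_ratio, per_class = TRUE)
  cal <- subset_samples(pre, split$calibration_ids)
  prd <- subset_samples(pre, split$prediction_ids)
  pca <- fit_pca(cal, k = cfg$n_components)
  sel_pca <- pick_loading_extrema(pca, n_components = cfg$n_components,
                                  threshold = cfg$loading_threshold,
                                  top_m = cfg$loading_top_m)
  d2 <- savitzky_golay(cal, cfg$sg_window, cfg$sg_polyorder, deriv = 2L)
  sel_d2 <- pick_derivative_extrema(d2, threshold = cfg$d2_threshold)
  feature_sets <- list(
    full = list(cal = cal, prd = prd),
    pca_loadings = NULL, second_derivative = NULL)
  for (nm in c("pca_loadings", "second_derivative")) {
    sel <- if (nm == "pca_loadings") sel_pca else sel_d2
    feature_sets[[nm]] <- tryCatch(
      list(cal = apply_selection(cal, sel), prd = apply_selection(prd, sel)),
      error = function(e) {
        message("skipping feature set ", nm, ": ", conditionMessage(e))
        NULL
      })
  }
  results <- list()
  for (nm in names(feature_sets)) {
    fs <- feature_sets[[nm]]
    if (is.null(fs)) next
    svm_m <- train_svm(fs$cal, c_grid = cfg$svm_c_grid,
                       g_grid = cfg$svm_g_grid, folds = cfg$cv_folds,
                       seed = cfg$seed)
    rbf_m <- train_rbf_net(fs$cal, spread_grid = cfg$rbf_spread_grid,
                           folds = cfg$cv_folds, seed = cfg$seed)
    elm_s <- search_elm(fs$cal, h_range = cfg$elm_h_range, seed = cfg$seed)
    results[[nm]] <- list(
      svm = list(calibration = evaluate(svm_m, fs$cal, "calibration"),
                 prediction = evaluate(svm_m, fs$prd, "prediction"),
                 params = list(c = svm_m$c, g = svm_m$g)),
      nn_rbf = list(calibration = evaluate(rbf_m, fs$cal, "calibration"),
                    prediction = evaluate(rbf_m, fs$prd, "prediction"),
                    params = list(s = rbf_m$spread)),
      elm = list(calibration = evaluate(elm_s$model, fs$cal, "calibration"),
                 prediction = evaluate(elm_s$model, fs$prd, "prediction"),
                 params = list(h = elm_s$h)))
  }
  out <- list(results = results,
              selections = list(pca_loadings = sel_pca,
                                second_derivative = sel_d2),
              split = split, data = pre, pca = pca)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_config_snapshot(cfg, outdir)
    write.csv(results_table(results),
              file.path(outdir, "model_results.csv"), row.names = FALSE)
    write.csv(selection_table(out$selections),
              file.path(outdir, "selected_wavelengths.csv"), row.names = FALSE)
    write.csv(data.frame(id = c(split$calibration_ids, split$prediction_ids),
                         set = rep(c("calibration", "prediction"),
                                   c(length(split$calibration_ids),
                                     length(split$prediction_ids)))),
              file.path(outdir, "split.csv"), row.names = FALSE)
  }
  out
}

#' Flatten nested model results into a table
#'
#' One row per feature set, model and set, mirroring the standard layout:
#' per-class accuracies then the macro mean, percentages to two decimals.
#'
#' @param results the `results` element of [run_objectwise()].
#' @return A data frame.
#' @export
results_table <- function(results) {
  rows <- list()
  for (fs in names(results)) for (mdl in names(results[[fs]])) {
    for (set in c("calibration", "prediction")) {
      rep <- results[[fs]][[mdl]][[set]]
      acc <- round(rep$per_class_accuracy, 2)
      row <- data.frame(feature_set = fs, model = mdl, set = set,
                        params = paste(names(results[[fs]][[mdl]]$params),
                                       unlist(results[[fs]][[mdl]]$params),
                                       sep = "=", collapse = ", "))
      for (cl in names(acc)) row[[paste0("class_", cl)]] <- acc[[cl]]
      row$mean <- round(rep$mean_accuracy, 2)
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

selection_table <- function(selections) {
  do.call(rbind, lapply(names(selections), function(nm) {
    s <- selections[[nm]]
    data.frame(source = nm, band_index = s$band_indices,
               wavelength_nm = round(s$wavelengths_nm, 2))
  }))
}

#' Summarize a completed run directory
#'
#' Collects whatever stage outputs are present under `run_dir` into a
#' Markdown summary (`report.md`); missing stages are listed rather than
#' failing, so partial runs still produce a partial report.
#'
#' @param run_dir directory written by [run_pixelwise()] / [run_objectwise()].
#' @return Path of the written report, invisibly.
#' @export
report_run <- function(run_dir) {
  if (!dir.exists(run_dir)) stop_bad_arg("run directory not found: ", run_dir)
  lines <- c("# berrytrace run report", "")
  missing <- character(0)
  ev <- file.path(run_dir, "explained_variance.csv")
  if (file.exists(ev)) {
    tab <- read.csv(ev)
    lines <- c(lines, "## Pixel-wise PCA", "",
               sprintf("- %d components, cumulative explained variance %.2f%%",
                       nrow(tab), sum(tab$explained_pct)),
               sprintf("- score images: %s",
                       paste(basename(Sys.glob(file.path(run_dir, "score_image_PC*.png"))),
                             collapse = ", ")), "")
  } else missing <- c(missing, "pixel-wise PCA")
  mr <- file.path(run_dir, "model_results.csv")
  if (file.exists(mr)) {
    tab <- read.csv(mr)
    for (cl in names(tab))
      if (is.numeric(tab[[cl]])) tab[[cl]] <- sprintf("%.2f", tab[[cl]])
    lines <- c(lines, "## Object-wise models", "",
               paste0("| ", paste(names(tab), collapse = " | "), " |"),
               paste0("|", paste(rep("---", ncol(tab)), collapse = "|"), "|"),
               vapply(seq_len(nrow(tab)), function(i)
                 paste0("| ", paste(unlist(tab[i, ]), collapse = " | "), " |"),
                 character(1)), "")
  } else missing <- c(missing, "object-wise models")
  sw <- file.path(run_dir, "selected_wavelengths.csv")
  if (file.exists(sw)) {
    tab <- read.csv(sw)
    lines <- c(lines, "## Selected wavelengths", "",
               vapply(split(tab, tab$source), function(g)
                 sprintf("- %s (%d): %s nm", g$source[1], nrow(g),
                         paste(round(g$wavelength_nm), collapse = ", ")),
                 character(1)), "")
  } else missing <- c(missing, "wavelength selection")
  if (length(missing))
    lines <- c(lines, "## Missing stages", "", paste("-", missing), "")
  path <- file.path(run_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
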