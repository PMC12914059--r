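# End-to-end orchestration: configuration, simulation studies (subtype
# dynamics, sample composition), frame-count sweep, artifact writing.

#' Pipeline run configuration
#'
#' @param scene A [scene_config()].
#' @param train A [train_config()].
#' @param f_min Low-frequency cutoff (Hz) for the dynamic analysis.
#' @param stages Character vector of stages to run, from
#'   `c("simulate", "segment", "features", "dynamics", "classify")`.
#' @param write_stack Write the rendered stack as a multi-page TIFF
#'   (large; off by default).
#' @param seed Master seed recorded with the run.
#' @return Object of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), train = train_config(),
                       f_min = 0.1,
                       stages = c("simulate", "segment", "features",
                                  "dynamics", "classify"),
                       write_stack = FALSE, seed = 1L) {
  known <- c("simulate", "segment", "features", "dynamics", "classify")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(scene = scene, train = train, f_min = f_min,
                 stages = stages, write_stack = write_stack,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration as JSON
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$scene <- unclass(x$scene)
  x$scene$class_mix <- as.list(x$scene$class_mix)  # keep names in JSON
  x$train <- unclass(x$train)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(scene_config, c(x$scene[setdiff(names(x$scene), "class_mix")],
                                list(class_mix = unlist(x$scene$class_mix))))
  tr <- do.call(train_config, x$train)
  run_config(scene = sc, train = tr, f_min = x$f_min, stages = x$stages,
             write_stack = isTRUE(x$write_stack), seed = x$seed)
}

.log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline into a directory
#'
#' Simulates a scene and stack, segments the first frame, extracts static
#' features (with chi-square ranking and, when enough cells are present, a
#' UMAP embedding), computes dynamic maps and cellwise dynamic features,
#' classifies viability/activation and subtype with the baseline classifier
#' where at least two of the relevant classes are present, and writes all
#' artifacts (TIFF masks/maps, CSV tables, pseudocolor PNGs, metrics JSON,
#' log). Re-running with the same config reproduces all numeric outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`scene`, `mask`,
#'   `features`, `dynamics`, `metrics`, ...).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  res <- list(config = config)
  metrics <- list(seed = config$seed)
  write_run_config(config, file.path(out_dir, "config.json"))
  st <- function(s) s %in% config$stages
  if (!st("simulate"))
    stop("the 'simulate' stage is the pipeline's data source and must be enabled")

  if (st("simulate")) {
    .log_line(logf, "simulate: ", config$scene$n_cells, " cells, ",
              config$scene$n_frames, " frames")
    res$scene <- make_scene(config$scene)
    write.csv(res$scene$truth$cells, file.path(out_dir, "cells_truth.csv"),
              row.names = FALSE)
    write_stack_tiff(res$scene$truth$label_mask,
                     file.path(out_dir, "truth_labels.tiff"))
    tiff::writeTIFF(res$scene$frame, file.path(out_dir, "frame.tiff"),
                    bits.per.sample = 32L)
    if (st("dynamics") || config$write_stack) {
      res$stack <- render_stack(config$scene, res$scene)
      if (config$write_stack)
        write_stack_tiff(res$stack, file.path(out_dir, "stack.tiff"))
    }
  }
  corrected <- background_correct(res$scene$frame)

  if (st("segment")) {
    .log_line(logf, "segment")
    res$mask <- segment_cells(corrected)
    write_stack_tiff(res$mask, file.path(out_dir, "labels.tiff"))
    mm <- match_labels(res$mask, res$scene$truth$label_mask)
    res$label_match <- mm
    metrics$n_cells_truth <- nrow(res$scene$truth$cells)
    metrics$n_cells_segmented <- max(res$mask)
    metrics$mean_iou <- mean(mm$iou)
  }

  if (st("features")) {
    .log_line(logf, "features: ", max(res$mask), " cells")
    ft <- feature_table(corrected, res$mask,
                        pixel_size = config$scene$pixel_size)
    lab <- res$label_match$truth[match(ft$cell, res$label_match$seg)]
    ft$class <- res$scene$truth$cells$class[lab]
    write.csv(ft, file.path(out_dir, "features_static.csv"), row.names = FALSE)
    res$features <- ft
    cls <- ft$class[ft$valid]
    if (length(unique(cls)) >= 2) {
      rk <- rank_features_chi2(ft[ft$valid, ], cls, top = 12)
      write.csv(rk, file.path(out_dir, "feature_ranking.csv"),
                row.names = FALSE)
      res$ranking <- rk
    }
    if (sum(ft$valid) >= 16) {
      emb <- embed_2d(ft[ft$valid, ], seed = config$seed)
      write.csv(data.frame(cell = ft$cell[ft$valid], umap1 = emb[, 1],
                           umap2 = emb[, 2], class = ft$class[ft$valid]),
                file.path(out_dir, "embedding.csv"), row.names = FALSE)
      res$embedding <- emb
    }
  }

  if (st("dynamics")) {
    .log_line(logf, "dynamics: pixelwise maps")
    maps <- dynamic_maps(res$stack, res$mask, f_min = config$f_min)
    res$dynamics <- maps
    for (nm in c("g", "s", "beta")) {
      m <- maps[[nm]]; m[!is.finite(m)] <- 0
      rng <- range(m)
      if (diff(rng) > 0) m <- (m - rng[1]) / diff(rng)
      tiff::writeTIFF(m, file.path(out_dir, paste0("map_", nm, ".tiff")),
                      bits.per.sample = 32L)
    }
    if (requireNamespace("png", quietly = TRUE)) {
      png::writePNG(pseudocolor(maps$beta, c(1, 2), mask = res$mask),
                    file.path(out_dir, "beta_pseudocolor.png"))
      gs <- maps$g * maps$s
      rng <- range(gs[res$mask > 0], na.rm = TRUE)
      if (diff(rng) > 0)
        png::writePNG(pseudocolor(gs, rng, mask = res$mask),
                      file.path(out_dir, "phasor_gs_pseudocolor.png"))
    }
    rows <- lapply(sort(unique(res$mask[res$mask > 0])), function(k) {
      cm <- res$mask == k
      crop_vals <- corrected; crop_vals[!cm] <- 0
      ns <- segment_nucleus(crop_vals, cell_mask = cm)
      cbind(cell = k, aggregate_cell_dynamics(maps, cm, ns$nucleus))
    })
    dyn <- do.call(rbind, rows)
    dyn$class <- res$features$class[match(dyn$cell, res$features$cell)]
    write.csv(dyn, file.path(out_dir, "features_dynamic.csv"),
              row.names = FALSE)
    res$dyn_features <- dyn
  }

  if (st("classify")) {
    ft <- res$features[res$features$valid & !is.na(res$features$class), ]
    viab <- ft[ft$class %in% c("activated", "quiescent", "dead"), ]
    if (length(unique(viab$class)) >= 2 && nrow(viab) >= 10) {
      .log_line(logf, "classify: viability/activation baseline")
      cv <- cross_validate(viab, viab$class,
                           config = .folds_for(config$train, viab$class))
      metrics$static_cv_accuracy <- cv$accuracy
    }
    if (!is.null(res$dyn_features)) {
      dyn <- res$dyn_features[!is.na(res$dyn_features$class) &
                                res$dyn_features$class %in%
                                c("CD4-like", "CD8-like"), ]
      if (length(unique(dyn$class)) >= 2 && nrow(dyn) >= 10) {
        .log_line(logf, "classify: subtype baseline")
        cv <- cross_validate(dyn, dyn$class,
                             config = .folds_for(config$train, dyn$class))
        metrics$subtype_cv_accuracy <- cv$accuracy
      }
    }
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  res$metrics <- metrics
  .log_line(logf, "done")
  invisible(res)
}

# Cap folds at the smallest class count so tiny demo scenes still cross-validate.
.folds_for <- function(train, labels) {
  k <- min(table(labels))
  if (k < train$folds) train$folds <- max(2L, as.integer(k))
  train
}

#' Simulate single-cell dynamic stacks and extract cellwise dynamic features
#'
#' Renders one small field per cell (500 frames at 8 Hz by default), runs the
#' pixelwise frequency analysis on the ground-truth cell mask, and aggregates
#' phasor and power-law features by compartment using the ground-truth nucleus
#' mask. This is the workhorse for subtype population studies.
#'
#' @param n_per_class Cells per class.
#' @param classes Classes to simulate (default CD4-like and CD8-like).
#' @param seed Base seed; cell i of class j uses `seed + 1000*j + i`.
#' @param n_frames,frame_rate,pixel_size Acquisition parameters.
#' @param f_min Low-frequency cutoff (Hz).
#' @param degrade Optional integer factor: degrade each stack's lateral
#'   resolution before analysis.
#' @param truncate Optional frame count: analyze only the first frames.
#' @return Data frame: `class`, `cell` and the [aggregate_cell_dynamics()]
#'   columns.
#' @export
simulate_subtype_cells <- function(n_per_class = 50,
                                   classes = c("CD4-like", "CD8-like"),
                                   seed = 1L, n_frames = 500, frame_rate = 8,
                                   pixel_size = 0.2, f_min = 0.1,
                                   degrade = NULL, truncate = NULL) {
  rows <- list()
  for (j in seq_along(classes)) {
    for (i in seq_len(n_per_class)) {
      mix <- setNames(1, classes[j])
      cfg <- scene_config(image_height = 64, image_width = 64,
                          pixel_size = pixel_size, n_cells = 1,
                          class_mix = mix, seed = seed + 1000L * j + i,
                          frame_rate = frame_rate, n_frames = n_frames)
      sc <- make_scene(cfg)
      stk <- render_stack(cfg, sc)
      cm <- sc$truth$label_mask == 1
      nm <- sc$truth$nucleus_mask == 1
      if (!is.null(truncate)) stk <- truncate_stack(stk, truncate)
      if (!is.null(degrade)) {
        stk <- degrade_resolution(stk, degrade)
        f <- as.integer(degrade)
        cm <- cm[seq(1, nrow(cm), by = f), seq(1, ncol(cm), by = f)]
        nm <- nm[seq(1, nrow(nm), by = f), seq(1, ncol(nm), by = f)]
      }
      maps <- dynamic_maps(stk, cm, f_min = f_min)
      rows[[length(rows) + 1]] <-
        cbind(class = classes[j], cell = i,
              aggregate_cell_dynamics(maps, cm, nm))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a composition study: known sample mixes vs predicted composition
#'
#' Trains the 3-class baseline on segmented cells from balanced training
#' scenes (labels transferred from ground truth by majority overlap), then
#' simulates `n_samples` fields with random viability/activation mixes,
#' segments them, predicts each cell's class and compares predicted sample
#' composition against the realized ground-truth composition.
#'
#' @param n_samples Number of simulated samples (default 20).
#' @param cells_per_sample Cells per sample field.
#' @param n_train_scenes Balanced training fields (same size).
#' @param seed Base seed.
#' @param pixel_size Micrometers per pixel.
#' @return List with `samples` (per-sample true/predicted percentages),
#'   `viability_fit` and `activation_fit` ([agreement_fit()] results) and the
#'   fitted `model`.
#' @export
simulate_composition_study <- function(n_samples = 20, cells_per_sample = 60,
                                       n_train_scenes = 4, seed = 1L,
                                       pixel_size = 0.2) {
  field <- 800L
  collect <- function(mix, sc_seed) {
    cfg <- scene_config(image_height = field, image_width = field,
                        pixel_size = pixel_size, n_cells = cells_per_sample,
                        class_mix = mix, seed = sc_seed, n_frames = 2)
    sc <- make_scene(cfg)
    corrected <- background_correct(sc$frame)
    mask <- segment_cells(corrected)
    ft <- feature_table(corrected, mask, pixel_size = pixel_size)
    mm <- match_labels(mask, sc$truth$label_mask)
    good <- mm$seg[mm$iou >= 0.5]
    ft <- ft[ft$valid & ft$cell %in% good, ]
    ft$class <- sc$truth$cells$class[mm$truth[match(ft$cell, mm$seg)]]
    list(features = ft, truth = sc$truth$cells)
  }
  balanced <- c(activated = 1 / 3, quiescent = 1 / 3, dead = 1 / 3)
  train <- do.call(rbind, lapply(seq_len(n_train_scenes), function(i)
    collect(balanced, seed + i)$features))
  model <- baseline_classifier(train[, !(names(train) %in% "class")],
                               train$class)
  set.seed(seed + 5000L)
  dead_frac <- runif(n_samples, 0.05, 0.7)
  act_frac <- runif(n_samples, 0.1, 0.9)
  samples <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    mix <- c(dead = dead_frac[i],
             activated = (1 - dead_frac[i]) * act_frac[i],
             quiescent = (1 - dead_frac[i]) * (1 - act_frac[i]))
    got <- collect(mix, seed + 100L + i)
    truth_cl <- got$truth$class
    true_viab <- 100 * mean(truth_cl != "dead")
    true_act <- 100 * sum(truth_cl == "activated") /
      sum(truth_cl %in% c("activated", "quiescent"))
    pred <- predict_composition(model,
                                got$features[, !(names(got$features) %in%
                                                   "class")])
    data.frame(sample = i, true_viability = true_viab,
               pred_viability = pred$viability_pct,
               true_activation = true_act,
               pred_activation = pred$activation_pct)
  }))
  list(samples = samples,
       viability_fit = agreement_fit(samples$pred_viability,
                                     samples$true_viability),
       activation_fit = agreement_fit(samples$pred_activation,
                                      samples$true_activation),
       model = model)
}

#' Subtype classification accuracy versus number of frames
#'
#' For each requested frame count, regenerates the single-cell stacks
#' (deterministic for the seed), truncates them to the count, recomputes the
#' dynamic features and cross-validates the baseline subtype classifier.
#'
#' @param frame_counts Integer vector of frame counts (each >= 8 and <=
#'   `n_frames`).
#' @param n_per_class Cells per subtype.
#' @param seed Base seed.
#' @param n_frames Full stack length.
#' @param folds Cross-validation folds.
#' @return Data frame: `n_frames`, `accuracy`.
#' @export
frame_sweep <- function(frame_counts = c(500, 300, 100, 32),
                        n_per_class = 30, seed = 1L, n_frames = 500,
                        folds = 5) {
  if (any(frame_counts < 8 | frame_counts > n_frames))
    stop("frame counts must lie in [8, n_frames]")
  do.call(rbind, lapply(frame_counts, function(nc) {
    feats <- simulate_subtype_cells(n_per_class = n_per_class, seed = seed,
                                    n_frames = n_frames, truncate = nc)
    cv <- cross_validate(feats[, .model_columns(feats), drop = FALSE],
                         feats$class,
                         config = train_config(folds = folds, seed = seed))
    data.frame(n_frames = nc, accuracy = cv$accuracy)
  }))
}
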