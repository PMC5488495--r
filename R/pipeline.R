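#' Detector configuration
#'
#' Stage parameters shared by training and detection: component-tree
#' construction, feature extraction, and classifier training.
#'
#' @param min_area,max_area Region area bounds in pixels (`NULL` max =
#'   1% of the image area).
#' @param n_levels Quantization levels for the component tree.
#' @param max_variation,stability_delta,min_diversity Stability (MSER)
#'   selection passed to [build_forest()]; the default keeps only maximally
#'   stable regions under a lenient variation threshold and deduplicates
#'   nested near-equal regions.
#' @param polarity `"bright"` or `"dark"` regions.
#' @param features A [feature_config()].
#' @param model A [model_config()].
#' @param transductive Include test-image paths in the unsupervised loss?
#' @return List of class `detector_config`.
#' @export
detector_config <- function(min_area = 30L, max_area = NULL, n_levels = 256L,
                            max_variation = 1, stability_delta = 5L,
                            min_diversity = 0.2,
                            polarity = c("bright", "dark"),
                            features = feature_config(),
                            model = model_config(), transductive = FALSE) {
  polarity <- match.arg(polarity)
  structure(list(min_area = as.integer(min_area), max_area = max_area,
                 n_levels = as.integer(n_levels),
                 max_variation = max_variation,
                 stability_delta = as.integer(stability_delta),
                 min_diversity = min_diversity,
                 polarity = polarity, features = features, model = model,
                 transductive = transductive), class = "detector_config")
}

# Forest + features for one image (optionally on a probability map), shared
# between training and detection so the benchmark computes them once.
prepare_image <- function(image, config, pixel_model = NULL,
                          norm_dim = NULL) {
  map <- if (is.null(pixel_model)) image else
    predict_probability_map(pixel_model, image)
  forest <- build_forest(map, min_area = config$min_area,
                         max_area = config$max_area,
                         polarity = config$polarity,
                         n_levels = config$n_levels,
                         max_variation = config$max_variation %||% Inf,
                         stability_delta = config$stability_delta %||% 5L,
                         min_diversity = config$min_diversity %||% 0.2)
  X <- region_features(forest, image, config$features, norm_dim = norm_dim)
  list(forest = forest, X = X, image = image)
}

#' Train a cell detector from annotated windows and unlabeled images
#'
#' Candidate regions and features are computed on the full training images;
#' supervision comes from subimage windows with dot annotations
#' ([window_supervision()]), so the supervised feature rows are rows of the
#' same matrices the unsupervised path-consistency loss operates on. The
#' feature standardizer is fitted on all training regions. With
#' `arm = "ss"` the unlabeled training images (and, in the transductive
#' setting, the test images) contribute root-to-leaf paths to the
#' unsupervised loss; with `arm = "supervised"` phase 2 simply continues
#' supervised training.
#'
#' Crops without a resolvable source preparation (no `window$image_idx`
#' into `prepared`) fall back to building a forest on the crop image
#' itself, with area bounds and feature normalization taken from the full
#' image geometry.
#'
#' @param crops Annotated windows from [sample_crops()] (each with `dots`,
#'   `window`, and `image`).
#' @param unlabeled List of training image matrices (used to build the
#'   shared forests/features when `prepared` is not given).
#' @param config A [detector_config()].
#' @param pixel_model Optional pixel classifier; when given, component
#'   trees are built on its probability maps.
#' @param test_images Unlabeled test images, used only if
#'   `config$transductive`.
#' @param prepared Optional precomputed forest/feature preparations for
#'   the training images (`prepared_test` for `test_images`), e.g. from a
#'   benchmark that reuses them across repeats.
#' @param prepared_test See `prepared`.
#' @param arm `"ss"` (semisupervised, default) or `"supervised"`.
#' @return Object of class `detector_checkpoint`: the trained model, the
#'   fitted standardizer, and the tree/feature parameters needed to apply
#'   it to new images.
#' @export
train_detector <- function(crops, unlabeled = list(),
                           config = detector_config(), pixel_model = NULL,
                           test_images = list(), prepared = NULL,
                           prepared_test = NULL, arm = c("ss", "supervised")) {
  stopifnot(inherits(config, "detector_config"), length(crops) >= 1)
  arm <- match.arg(arm)
  if (is.null(config$max_area)) {
    # Resolve the 1%-of-image default against the full images so that any
    # crop-level fallback uses the same absolute area bounds.
    ref <- if (length(unlabeled)) unlabeled[[1]] else
      if (!is.null(prepared) && length(prepared)) prepared[[1]]$image else
        crops[[1]]$image
    config$max_area <- max(config$min_area, ceiling(0.01 * length(ref)))
  }
  if (is.null(prepared) && length(unlabeled) > 0)
    prepared <- lapply(unlabeled, prepare_image, config = config,
                       pixel_model = pixel_model)

  X_s_list <- list(); y_s_list <- list()
  for (cr in crops) {
    idx <- cr$window$image_idx
    if (!is.null(idx) && !is.null(prepared) && !is.na(idx) &&
        idx >= 1 && idx <= length(prepared)) {
      p <- prepared[[idx]]
      gdots <- data.frame(row = cr$dots$row + cr$window$row0,
                          col = cr$dots$col + cr$window$col0)
      ws <- window_supervision(p$forest, gdots, cr$window)
      X_s_list[[length(X_s_list) + 1L]] <- p$X[ws$ids, , drop = FALSE]
      y_s_list[[length(y_s_list) + 1L]] <- ws$labels
    } else {
      p <- prepare_image(cr$image, config, pixel_model,
                         norm_dim = cr$source_dim)
      X_s_list[[length(X_s_list) + 1L]] <- p$X
      y_s_list[[length(y_s_list) + 1L]] <- induce_region_labels(p$forest, cr$dots)
    }
  }
  X_s <- do.call(rbind, X_s_list)
  y_s <- unlist(y_s_list)
  if (is.null(X_s) || nrow(X_s) == 0)
    stopf("annotated windows contain no candidate regions")

  unsup_prep <- if (arm == "ss") prepared else list()
  if (arm == "ss" && config$transductive && length(test_images) > 0) {
    if (is.null(prepared_test))
      prepared_test <- lapply(test_images, prepare_image, config = config,
                              pixel_model = pixel_model)
    unsup_prep <- c(unsup_prep, prepared_test)
  }
  X_u_list <- lapply(unsup_prep, `[[`, "X")
  X_u <- if (length(X_u_list)) do.call(rbind, X_u_list) else NULL
  paths <- list()
  offset <- 0L
  for (p in unsup_prep) {
    for (pa in enumerate_paths(p$forest)) paths[[length(paths) + 1L]] <- pa + offset
    offset <- offset + nrow(p$X)
  }

  std_X <- rbind(X_s, X_u,
                 if (arm == "supervised" && !is.null(prepared))
                   do.call(rbind, lapply(prepared, `[[`, "X")))
  std <- fit_standardizer(std_X)
  model <- train_model(apply_standardizer(X_s, std), y_s,
                       if (!is.null(X_u)) apply_standardizer(X_u, std),
                       paths, config$model)
  structure(list(model = model, standardizer = std,
                 feature_config = config$features,
                 tree_params = list(min_area = config$min_area,
                                    max_area = config$max_area,
                                    polarity = config$polarity,
                                    n_levels = config$n_levels,
                                    max_variation = config$max_variation,
                                    stability_delta = config$stability_delta,
                                    min_diversity = config$min_diversity),
                 n_supervised = length(y_s), n_paths = length(paths),
                 arm = arm, transductive = config$transductive),
            class = "detector_checkpoint")
}

#' @export
print.detector_checkpoint <- function(x, ...) {
  cat(sprintf(paste0("detector checkpoint: %d supervised regions, %d paths,",
                     " sigma_s=%.3g, sigma_u=%.3g\n"),
              x$n_supervised, x$n_paths, x$model$sigma_s, x$model$sigma_u))
  invisible(x)
}

#' Persist / load a detector checkpoint
#'
#' @param checkpoint A `detector_checkpoint`.
#' @param path Destination file (RDS).
#' @return `write_checkpoint`: invisibly `path`; `read_checkpoint`: the
#'   checkpoint.
#' @export
write_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "detector_checkpoint"))
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!inherits(ck, "detector_checkpoint"))
    stopf("'%s' is not a detector checkpoint", path)
  ck
}

# Detection on a prepared image (reuses forest/features).
detect_prepared <- function(prep, checkpoint, method = "dp") {
  forest <- prep$forest
  if (nrow(prep$X) == 0) {
    det <- make_detections(forest, integer(0), NULL, method)
  } else {
    Xs <- apply_standardizer(prep$X, checkpoint$standardizer)
    scores <- score_region(checkpoint$model$params, Xs)
    det <- if (method == "greedy") greedy_infer(forest, scores) else
      top_down_labels(forest, bottom_up_energies(forest, scores), scores)
    det$scores <- scores
  }
  det$forest <- forest
  det
}

#' Benchmark configuration
#'
#' The synthetic benchmark mirrors the reduced-supervision protocol: a pool
#' of subimage crops (about 1/8 of the image area) is built over the
#' training scenes, `k` crops are drawn at random per repeat, and each
#' training arm is scored on held-out test scenes by Hungarian matching of
#' detected centroids to ground-truth dots.
#'
#' @param n_scenes Total scenes generated.
#' @param n_train Scenes used for training (crop pool + unsupervised
#'   paths); the rest are test scenes.
#' @param scene A [scene_spec()] template (its seed is replaced per scene).
#' @param ks Numbers of labeled subimages to evaluate.
#' @param n_repeats Seeded repeats per cell of the grid (random crop
#'   draws).
#' @param arms Subset of `"supervised"` (supervised loss only), `"ss"`
#'   (semisupervised on intensity trees), `"ss_pixel"` (semisupervised on
#'   pixel-probability trees).
#' @param transductive Also include test-scene paths in the unsupervised
#'   loss.
#' @param detector A [detector_config()].
#' @param max_distance Matching gate in pixels; `NULL` means the mean cell
#'   radius of the scene template.
#' @param seed Master seed for scene generation and crop draws.
#' @return List of class `benchmark_config`.
#' @export
benchmark_config <- function(n_scenes = 20L, n_train = 8L,
                             scene = scene_spec_easy(), ks = 1L,
                             n_repeats = 5L,
                             arms = c("supervised", "ss"),
                             transductive = FALSE, detector = NULL,
                             max_distance = NULL, seed = 1L) {
  stopifnot(n_train >= 1, n_scenes > n_train)
  arms <- match.arg(arms, c("supervised", "ss", "ss_pixel"), several.ok = TRUE)
  if (is.null(detector)) {
    # Area bounds follow the scene geometry: candidates from half the
    # smallest cell up to ~2.5x the largest (room for touching pairs).
    detector <- detector_config(
      min_area = max(10L, floor(0.4 * pi * min(scene$radius_range)^2)),
      max_area = ceiling(2.5 * pi * max(scene$radius_range)^2),
      min_diversity = 0.5, polarity = scene$polarity,
      model = model_config(step_rule = "backtrack", sigma_floor = 0.2))
  }
  if (is.null(max_distance)) max_distance <- mean(scene$radius_range)
  structure(list(n_scenes = as.integer(n_scenes), n_train = as.integer(n_train),
                 scene = scene, ks = as.integer(ks),
                 n_repeats = as.integer(n_repeats), arms = arms,
                 transductive = transductive, detector = detector,
                 max_distance = max_distance, seed = as.integer(seed)),
            class = "benchmark_config")
}

#' Run the synthetic detection benchmark
#'
#' Generates the scenes, precomputes component trees and features once,
#' then for every combination of labeled-subimage count `k`, repeat, and
#' training arm trains a detector and scores it on the test scenes.
#'
#' @param config A [benchmark_config()].
#' @param methods Inference methods to evaluate (`"dp"`, `"greedy"`).
#' @return data.frame with one row per (k, repeat, arm, method):
#'   `precision`, `recall`, `f_score`, `dice`.
#' @export
benchmark_run <- function(config = benchmark_config(), methods = "dp") {
  stopifnot(inherits(config, "benchmark_config"))
  scenes <- lapply(seq_len(config$n_scenes), function(i) {
    sp <- config$scene
    sp$seed <- config$seed * 1000L + i
    generate_scene(sp)
  })
  train_idx <- seq_len(config$n_train)
  test_idx <- setdiff(seq_len(config$n_scenes), train_idx)
  dcfg <- config$detector
  dcfg$transductive <- config$transductive
  if (is.null(dcfg$max_area))
    dcfg$max_area <- max(dcfg$min_area,
                         ceiling(0.01 * config$scene$image_height *
                                   config$scene$image_width))

  prep_train <- lapply(scenes[train_idx], function(s)
    prepare_image(s$image, dcfg))
  prep_test <- lapply(scenes[test_idx], function(s)
    prepare_image(s$image, dcfg))

  pixel_model <- NULL
  prep_train_px <- prep_test_px <- NULL
  if ("ss_pixel" %in% config$arms) {
    idx2 <- train_idx[seq_len(min(2L, length(train_idx)))]
    if (length(idx2) < 2) stopf("ss_pixel arm needs at least two training scenes")
    # Dense fields: a narrower negative Gaussian with a higher cutoff has
    # the same "far from every cell" semantics while leaving feasible
    # background pixels between cells.
    samp <- lapply(scenes[idx2], function(s)
      sample_training_pixels(s$dots, dim(s$image),
                             density_sampling_params(
                               sigma_neg = 1.5 * mean(config$scene$radius_range),
                               neg_threshold = 0.3),
                             seed = config$seed))
    pixel_model <- train_pixel_classifier(lapply(scenes[idx2], `[[`, "image"),
                                          samp, polarity = config$scene$polarity,
                                          seed = config$seed)
    prep_train_px <- lapply(scenes[train_idx], function(s)
      prepare_image(s$image, dcfg, pixel_model))
    prep_test_px <- lapply(scenes[test_idx], function(s)
      prepare_image(s$image, dcfg, pixel_model))
  }

  pool <- make_subimage_pool(scenes[train_idx], seed = config$seed)
  check_prep <- if (!is.null(prep_train_px) && !("ss" %in% config$arms) &&
                    !("supervised" %in% config$arms)) prep_train_px else prep_train
  rows <- list()
  for (k in config$ks) {
    for (rep in seq_len(config$n_repeats)) {
      # a draw whose pooled window supervision lacks one of the two region
      # classes is unusable for training; redraw deterministically
      crops <- NULL
      for (attempt in 0:49) {
        cand <- sample_crops(pool, k,
                             seed = config$seed * 100L + rep * 7L + k +
                               attempt * 7919L)
        labs <- unlist(lapply(cand, function(cr) {
          p <- check_prep[[cr$window$image_idx]]
          window_supervision(p$forest,
                             data.frame(row = cr$dots$row + cr$window$row0,
                                        col = cr$dots$col + cr$window$col0),
                             cr$window)$labels
        }))
        if (length(unique(labs)) == 2) { crops <- cand; break }
      }
      if (is.null(crops))
        stopf("no usable subimage draw found (need both region classes)")
      for (arm in config$arms) {
        px <- if (arm == "ss_pixel") pixel_model else NULL
        prep_u <- switch(arm, supervised = prep_train, ss = prep_train,
                         ss_pixel = prep_train_px)
        prep_t <- switch(arm, supervised = prep_test, ss = prep_test,
                         ss_pixel = prep_test_px)
        mcfg <- dcfg
        mcfg$model$seed <- config$seed * 100L + rep * 7L + k
        ck <- train_detector(
          crops, config = mcfg, pixel_model = px,
          test_images = if (arm == "supervised") list() else
            lapply(scenes[test_idx], `[[`, "image"),
          prepared = prep_u, prepared_test = prep_t,
          arm = if (arm == "supervised") "supervised" else "ss")
        for (method in methods) {
          dets <- lapply(prep_t, detect_prepared, checkpoint = ck,
                         method = method)
          ev <- evaluate_detections(dets, scenes[test_idx],
                                    config$max_distance)
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, rep = rep, arm = arm, method = method,
            transductive = config$transductive,
            precision = ev$precision, recall = ev$recall,
            f_score = ev$f_score, dice = ev$dice)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a benchmark table
#'
#' @param results [benchmark_run()] output.
#' @return data.frame with mean and standard deviation of the F-score per
#'   (k, arm, method).
#' @export
benchmark_summary <- function(results) {
  agg <- aggregate(f_score ~ k + arm + method + transductive, results,
                   function(v) c(mean = mean(v), sd = stats::sd(v)))
  out <- cbind(agg[, c("k", "arm", "method", "transductive")],
               f_mean = agg$f_score[, "mean"], f_sd = agg$f_score[, "sd"])
  out$f_sd[is.na(out$f_sd)] <- 0
  out
}
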