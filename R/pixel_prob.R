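#' Gaussian density map of dot annotations
#'
#' Superposition of isotropic Gaussians, one per dot, each with peak value 1
#' at its cell centre. With a small standard deviation the map is close to 1
#' only near centres (used to harvest positive pixel samples); with a large
#' one it decays slowly, so pixels where it is still near 0 are reliably
#' background (negative samples).
#'
#' @param dots data.frame with zero-based `row`, `col` centres.
#' @param shape Image dimensions `c(H, W)`.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Numeric `H x W` matrix.
#' @export
density_map <- function(dots, shape, sigma) {
  H <- shape[1]; W <- shape[2]
  stopifnot(sigma > 0)
  out <- matrix(0, H, W)
  if (nrow(dots) == 0) return(out)
  if (any(dots$row < 0 | dots$row >= H | dots$col < 0 | dots$col >= W))
    stopf("dot outside image bounds")
  rows <- 0:(H - 1); cols <- 0:(W - 1)
  for (i in seq_len(nrow(dots))) {
    gr <- exp(-(rows - dots$row[i])^2 / (2 * sigma^2))
    gc <- exp(-(cols - dots$col[i])^2 / (2 * sigma^2))
    out <- out + outer(gr, gc)
  }
  out
}

#' Density-based sampling parameters
#'
#' @param sigma_pos Small Gaussian width (px) for positive sampling.
#' @param sigma_neg Large Gaussian width (px) for negative sampling;
#'   typically about three times the mean cell radius.
#' @param pos_threshold Density at or above which a pixel is a positive
#'   sample.
#' @param neg_threshold Density at or below which a pixel is a negative
#'   sample.
#' @param max_samples_per_class Per-image cap on samples of each class.
#' @return List of class `density_sampling_params`.
#' @export
density_sampling_params <- function(sigma_pos = 2, sigma_neg = 16,
                                    pos_threshold = 0.6, neg_threshold = 0.05,
                                    max_samples_per_class = 5000L) {
  if (!(sigma_pos < sigma_neg)) stopf("sigma_pos must be smaller than sigma_neg")
  if (any(c(pos_threshold, neg_threshold) <= 0) ||
      any(c(pos_threshold, neg_threshold) >= 1))
    stopf("thresholds must lie strictly in (0, 1)")
  structure(list(sigma_pos = sigma_pos, sigma_neg = sigma_neg,
                 pos_threshold = pos_threshold, neg_threshold = neg_threshold,
                 max_samples_per_class = as.integer(max_samples_per_class)),
            class = "density_sampling_params")
}

#' Sample training pixels from dot annotations
#'
#' Positives are pixels where the narrow-sigma density map reaches
#' `pos_threshold`; negatives are pixels where the wide-sigma map stays at
#' or below `neg_threshold`. Each class is subsampled to the configured cap.
#'
#' @param dots data.frame with zero-based `row`, `col`.
#' @param shape Image dimensions `c(H, W)`.
#' @param params A [density_sampling_params()].
#' @param seed Seed for the subsampling.
#' @return data.frame with zero-based `row`, `col` and `label` (1/0).
#' @export
sample_training_pixels <- function(dots, shape, params = density_sampling_params(),
                                   seed = 1L) {
  stopifnot(inherits(params, "density_sampling_params"))
  H <- shape[1]
  pos <- which(density_map(dots, shape, params$sigma_pos) >= params$pos_threshold)
  neg <- which(density_map(dots, shape, params$sigma_neg) <= params$neg_threshold)
  if (length(pos) == 0) stopf("no positive pixels at pos_threshold %.2f",
                              params$pos_threshold)
  if (length(neg) == 0) stopf("no negative pixels at neg_threshold %.2f",
                              params$neg_threshold)
  with_seed(seed, {
    cap <- params$max_samples_per_class
    if (length(pos) > cap) pos <- sort(sample(pos, cap))
    if (length(neg) > cap) neg <- sort(sample(neg, cap))
  })
  rc <- index_to_rc(c(pos, neg), H)
  rc$label <- rep(c(1L, 0L), c(length(pos), length(neg)))
  rc
}

#' Multi-scale filter-bank features per pixel
#'
#' Raw intensity plus, per Gaussian scale: smoothed intensity, gradient
#' magnitude, Laplacian, and the two eigenvalues of the Hessian.
#'
#' @param image Image matrix.
#' @param scales Gaussian scales in pixels.
#' @return Matrix with `H*W` rows (column-major pixel order).
#' @export
pixel_features <- function(image, scales = c(1, 2, 4)) {
  check_image(image)
  shift <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    r <- pmin(pmax(seq_len(H) + dr, 1L), H)
    c <- pmin(pmax(seq_len(W) + dc, 1L), W)
    m[r, c, drop = FALSE]
  }
  feats <- list(raw = as.vector(image))
  for (s in scales) {
    g <- gaussian_blur(image, s)
    gy <- (shift(g, 1, 0) - shift(g, -1, 0)) / 2
    gx <- (shift(g, 0, 1) - shift(g, 0, -1)) / 2
    gyy <- shift(g, 1, 0) + shift(g, -1, 0) - 2 * g
    gxx <- shift(g, 0, 1) + shift(g, 0, -1) - 2 * g
    gxy <- (shift(g, 1, 1) + shift(g, -1, -1) -
              shift(g, 1, -1) - shift(g, -1, 1)) / 4
    tr <- gxx + gyy
    det_rt <- sqrt(pmax((gxx - gyy)^2 + 4 * gxy^2, 0))
    feats[[paste0("smooth_", s)]] <- as.vector(g)
    feats[[paste0("gradmag_", s)]] <- as.vector(sqrt(gx^2 + gy^2))
    feats[[paste0("laplace_", s)]] <- as.vector(tr)
    feats[[paste0("hess1_", s)]] <- as.vector((tr + det_rt) / 2)
    feats[[paste0("hess2_", s)]] <- as.vector((tr - det_rt) / 2)
  }
  # filter responses are meaningful well above 1e-10; rounding removes
  # float noise from renormalized boundary kernels that tree splits could
  # otherwise latch onto
  round(do.call(cbind, feats), 10)
}

#' Train the pixel classifier
#'
#' Random forest over the multi-scale filter bank, trained on density-derived
#' pixel samples from at least two annotated images; fills the role of an
#' interactive pixel-classification stage with a seeded, scriptable model.
#'
#' @param images List of image matrices (values in \[0, 1\]).
#' @param samples List of data.frames from [sample_training_pixels()], one
#'   per image.
#' @param scales Filter-bank scales.
#' @param polarity `"bright"` or `"dark"`; dark images are inverted before
#'   filtering.
#' @param num_trees Forest size.
#' @param seed Seed controlling forest training.
#' @return Object of class `pixel_model`.
#' @export
train_pixel_classifier <- function(images, samples, scales = c(1, 2, 4),
                                   polarity = c("bright", "dark"),
                                   num_trees = 100L, seed = 1L) {
  polarity <- match.arg(polarity)
  if (length(images) < 2) stopf("at least two annotated images are required")
  if (length(samples) != length(images))
    stopf("need one sample table per image")
  Xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]
    check_image(img)
    if (polarity == "dark") img <- 1 - img
    fx <- pixel_features(img, scales)
    idx <- rc_to_index(samples[[i]]$row, samples[[i]]$col, nrow(img))
    Xs[[i]] <- fx[idx, , drop = FALSE]
    ys[[i]] <- samples[[i]]$label
  }
  X <- do.call(rbind, Xs)
  y <- factor(unlist(ys), levels = c(0, 1))
  if (length(unique(y)) < 2) stopf("training pixels contain a single class")
  df <- as.data.frame(X)
  df$.y <- y
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = num_trees, probability = TRUE,
                        seed = seed, num.threads = 1)
  structure(list(forest = fit, scales = scales, polarity = polarity,
                 feature_names = colnames(X)), class = "pixel_model")
}

#' Predict a cell-probability map
#'
#' @param model A [train_pixel_classifier()] model.
#' @param image Image matrix with the same value convention as training.
#' @return Numeric matrix in \[0, 1\], same shape as `image`.
#' @export
predict_probability_map <- function(model, image) {
  stopifnot(inherits(model, "pixel_model"))
  check_image(image)
  img <- if (model$polarity == "dark") 1 - image else image
  fx <- pixel_features(img, model$scales)
  if (!identical(colnames(fx), model$feature_names))
    stopf("feature configuration differs from the training configuration")
  pred <- stats::predict(model$forest, data = as.data.frame(fx),
                         num.threads = 1)$predictions
  matrix(pred[, "1"], nrow(image), ncol(image))
}

#' Persist / load a pixel model
#'
#' @param model A `pixel_model`.
#' @param path Destination file (RDS).
#' @return `write_pixel_model`: invisibly `path`; `read_pixel_model`: the
#'   model.
#' @export
write_pixel_model <- function(model, path) {
  stopifnot(inherits(model, "pixel_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_pixel_model
#' @export
read_pixel_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pixel_model")) stopf("'%s' is not a pixel model", path)
  m
}
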