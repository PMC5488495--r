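#' Feature configuration
#'
#' Defaults for the per-region descriptor: 16 intensity histogram bins,
#' border dilation radii 1 and 3 px, 16 angular bins for the polar shape
#' histogram, and a 5x5 texture window.
#'
#' @param n_bins Intensity histogram bins.
#' @param dilation_radii Two dilation radii (pixels) for border-contrast
#'   features.
#' @param n_angular_bins Angular bins of the polar shape histogram.
#' @param texture_window Side of the square texture window (odd).
#' @return A named list of class `feature_config`.
#' @export
feature_config <- function(n_bins = 16L, dilation_radii = c(1L, 3L),
                           n_angular_bins = 16L, texture_window = 5L) {
  stopifnot(n_bins >= 2, length(dilation_radii) == 2,
            n_angular_bins >= 4, texture_window %% 2 == 1)
  structure(list(n_bins = as.integer(n_bins),
                 dilation_radii = as.integer(dilation_radii),
                 n_angular_bins = as.integer(n_angular_bins),
                 texture_window = as.integer(texture_window)),
            class = "feature_config")
}

norm_hist <- function(v, n_bins) {
  b <- pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins)
  tabulate(b, n_bins) / length(v)
}

hist_entropy <- function(h) {
  p <- h[h > 0]
  -sum(p * log(p))
}

# Border pixels of a region: region pixels with a 4-neighbour outside the
# region (pixels on the image border count). Returns linear indices.
region_border <- function(pix, H, W) {
  inside <- logical(H * W)
  inside[pix] <- TRUE
  rc <- index_to_rc(pix, H)
  r <- rc$row; c <- rc$col
  out <- function(rr, cc) {
    bad <- rr < 0 | rr >= H | cc < 0 | cc >= W
    res <- logical(length(rr))
    res[bad] <- TRUE
    res[!bad] <- !inside[rc_to_index(rr[!bad], cc[!bad], H)]
    res
  }
  is_b <- out(r - 1L, c) | out(r + 1L, c) | out(r, c - 1L) | out(r, c + 1L)
  list(border = pix[is_b],
       crack_length = sum(out(r - 1L, c)) + sum(out(r + 1L, c)) +
         sum(out(r, c - 1L)) + sum(out(r, c + 1L)))
}

# Dilate a pixel set by a disc of radius rad within the image bounds.
dilate_pixels <- function(pix, H, W, rad) {
  rc <- index_to_rc(pix, H)
  off <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  off <- off[off$dr^2 + off$dc^2 <= rad^2, ]
  r <- outer(rc$row, off$dr, `+`)
  c <- outer(rc$col, off$dc, `+`)
  ok <- r >= 0 & r < H & c >= 0 & c < W
  unique(rc_to_index(r[ok], c[ok], H))
}

#' Intensity features of a region
#'
#' Normalized intensity histogram of the region plus border-contrast
#' statistics: for each of two dilation radii, the absolute mean
#' difference, L1 and L2 histogram distances, and absolute entropy
#' difference between the histogram of the region border and the histogram
#' of the border's dilation.
#'
#' @param pix Region pixel set (1-based linear indices).
#' @param image Source image matrix (values in \[0, 1\]).
#' @param config A [feature_config()].
#' @return Named numeric vector.
#' @export
intensity_features <- function(pix, image, config = feature_config()) {
  if (length(pix) == 0) stopf("empty region")
  H <- nrow(image); W <- ncol(image)
  nb <- config$n_bins
  h_region <- norm_hist(image[pix], nb)
  bord <- region_border(pix, H, W)
  vb <- image[bord$border]
  hb <- norm_hist(vb, nb)
  out <- setNames(h_region, paste0("int_hist_", seq_len(nb)))
  for (rad in config$dilation_radii) {
    dil <- dilate_pixels(bord$border, H, W, rad)
    vd <- image[dil]
    hd <- norm_hist(vd, nb)
    out <- c(out, setNames(
      c(abs(mean(vb) - mean(vd)), sum(abs(hb - hd)), sqrt(sum((hb - hd)^2)),
        abs(hist_entropy(hb) - hist_entropy(hd))),
      paste0(c("int_dmean_r", "int_l1_r", "int_l2_r", "int_dent_r"), rad)))
  }
  out
}

#' Area features of a region
#'
#' Region area normalized by the image area; border pixel count and crack
#' boundary length, both normalized by the image diagonal.
#'
#' @inheritParams intensity_features
#' @param dim Image dimensions `c(H, W)` (the array the pixel indices refer
#'   to).
#' @param norm_dim Reference dimensions used for the normalization; when a
#'   region comes from a training crop this is the source image's geometry,
#'   so crop and full-image features share one scale.
#' @return Named numeric vector.
#' @export
area_features <- function(pix, dim, norm_dim = dim) {
  if (length(pix) == 0) stopf("empty region")
  H <- dim[1]; W <- dim[2]
  bord <- region_border(pix, H, W)
  diag_len <- sqrt(norm_dim[1]^2 + norm_dim[2]^2)
  c(area_norm = length(pix) / (norm_dim[1] * norm_dim[2]),
    perimeter_norm = length(bord$border) / diag_len,
    boundary_norm = bord$crack_length / diag_len)
}

#' Shape features of a region
#'
#' A size-normalized polar boundary histogram (mean boundary radius per
#' angular bin, divided by the maximum radius), a curvature summary (mean
#' absolute second difference of the radius profile), and the roundness
#' ratio 4*pi*A/P^2 with the crack perimeter corrected by pi/4 for digital
#' overestimation. Regions below 5 px get a uniform histogram and zero
#' curvature.
#'
#' @inheritParams area_features
#' @return Named numeric vector.
#' @export
shape_features <- function(pix, dim, config = feature_config()) {
  if (length(pix) == 0) stopf("empty region")
  H <- dim[1]; W <- dim[2]
  na <- config$n_angular_bins
  bord <- region_border(pix, H, W)
  P <- bord$crack_length * pi / 4
  roundness <- if (P > 0) min(4 * pi * length(pix) / P^2, 1.5) else 0
  if (length(pix) < 5) {
    return(c(setNames(rep(1 / na, na), paste0("shape_polar_", seq_len(na))),
             shape_curvature = 0, shape_roundness = roundness))
  }
  rc <- index_to_rc(bord$border, H)
  ctr <- colMeans(index_to_rc(pix, H))
  dy <- rc$row - ctr[1]; dx <- rc$col - ctr[2]
  rho <- sqrt(dy^2 + dx^2)
  theta <- atan2(dx, dy) %% (2 * pi)
  bin <- pmin(floor(theta / (2 * pi) * na) + 1L, na)
  prof <- vapply(seq_len(na), function(b) {
    v <- rho[bin == b]
    if (length(v)) mean(v) else 0
  }, numeric(1))
  mx <- max(prof, max(rho), 1e-9)
  prof_n <- prof / mx
  curv <- mean(abs(diff(c(prof_n, prof_n[1:2]), differences = 2)))
  c(setNames(prof_n, paste0("shape_polar_", seq_len(na))),
    shape_curvature = curv, shape_roundness = roundness)
}

#' Texture maps of an image
#'
#' Per-pixel local standard deviation, local range, and local histogram
#' entropy in a square window; region texture features are means of these
#' maps over the region. Computed once per image and reused for all its
#' regions.
#'
#' @param image Image matrix in \[0, 1\].
#' @param config A [feature_config()].
#' @return List of three matrices `std`, `range`, `entropy`.
#' @export
texture_maps <- function(image, config = feature_config()) {
  check_image(image)
  k <- config$texture_window
  m1 <- box_mean(image, k)
  m2 <- box_mean(image^2, k)
  tstd <- sqrt(pmax(m2 - m1^2, 0))
  brush <- EBImage::makeBrush(k, "box")
  trange <- EBImage::dilate(image, brush) - EBImage::erode(image, brush)
  nlev <- 16L
  q <- pmin(pmax(floor(image * nlev) + 1L, 1L), nlev)
  ent <- matrix(0, nrow(image), ncol(image))
  for (l in seq_len(nlev)) {
    p <- box_mean((q == l) * 1, k)
    pos <- p > 0
    ent[pos] <- ent[pos] - p[pos] * log(p[pos])
  }
  list(std = tstd, range = as.matrix(trange), entropy = ent)
}

#' Texture features of a region
#'
#' @inheritParams intensity_features
#' @param tmaps Result of [texture_maps()] for the same image.
#' @return Named numeric vector: mean local entropy, std, and range.
#' @export
texture_features <- function(pix, tmaps) {
  if (length(pix) == 0) stopf("empty region")
  c(tex_entropy = mean(tmaps$entropy[pix]),
    tex_std = mean(tmaps$std[pix]),
    tex_range = mean(tmaps$range[pix]))
}

#' Assemble the full feature matrix for a forest
#'
#' Concatenates intensity, area, shape, and texture features plus a trailing
#' bias entry fixed at 1, for every region of a forest.
#'
#' @param forest A [build_forest()] result.
#' @param image The image the forest was built from (features are computed
#'   on the original intensities).
#' @param config A [feature_config()].
#' @param tmaps Optional precomputed [texture_maps()].
#' @param norm_dim Reference dimensions for the size normalization of the
#'   area features (defaults to the image's own); pass the source image's
#'   dimensions when featurizing a training crop.
#' @return Numeric matrix, one row per region; column names are the feature
#'   manifest, last column `bias`.
#' @export
region_features <- function(forest, image, config = feature_config(),
                            tmaps = NULL, norm_dim = NULL) {
  if (is.null(norm_dim)) norm_dim <- forest$dim
  stopifnot(inherits(forest, "region_forest"))
  check_image(image)
  if (!all(forest$dim == dim(image)))
    stopf("forest and image dimensions differ")
  n <- nrow(forest$nodes)
  if (n == 0) {
    dummy <- matrix(0.5, 4, 4)
    tm <- texture_maps(dummy, config)
    tmpl <- c(intensity_features(1L, dummy, config), area_features(1L, c(4, 4)),
              shape_features(1L, c(4, 4), config), texture_features(1L, tm),
              bias = 1)
    return(matrix(numeric(0), 0, length(tmpl),
                  dimnames = list(NULL, names(tmpl))))
  }
  if (is.null(tmaps)) tmaps <- texture_maps(image, config)
  rows <- lapply(seq_len(n), function(i) {
    pix <- forest$pixels[[i]]
    c(intensity_features(pix, image, config),
      area_features(pix, forest$dim, norm_dim),
      shape_features(pix, forest$dim, config),
      texture_features(pix, tmaps), bias = 1)
  })
  X <- do.call(rbind, rows)
  if (anyNA(X) || any(!is.finite(X))) stopf("non-finite feature values")
  X
}

#' Fit / apply feature standardization
#'
#' Z-scores every feature column except the trailing bias; constant columns
#' are left unscaled. Fitted on the training regions and applied to all
#' regions so the tanh classifier sees bounded inputs.
#'
#' @param X Feature matrix from [region_features()].
#' @return `fit_standardizer`: list with `center`, `scale`.
#' @export
fit_standardizer <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-8] <- 1
  nb <- ncol(X)
  ctr[nb] <- 0; scl[nb] <- 1  # keep the bias entry at 1
  list(center = ctr, scale = scl)
}

#' @rdname fit_standardizer
#' @param std A fitted standardizer.
#' @export
apply_standardizer <- function(X, std) {
  stopifnot(ncol(X) == length(std$center))
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}
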