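#' Specify a synthetic microscopy scene
#'
#' Bundles and validates the parameters of the synthetic scene generator.
#' Scenes emulate dense fields of roughly convex bright (or dark) cells on a
#' smoothly textured background: rotated ellipses with low-order radial
#' boundary jitter, per-cell intensities, additive Gaussian noise, and a
#' configurable fraction of cells placed touching a neighbour so that
#' candidate regions of merged cell pairs exist in the component tree.
#'
#' @param image_height,image_width Image size in pixels.
#' @param n_cells Number of cells to place (may be 0).
#' @param radius_range Length-2 numeric, min/max equivalent cell radius in
#'   pixels (the radius of the circle with the same area as the ellipse).
#'   Minimum must be at least 2.
#' @param eccentricity_range Length-2 numeric, min/max ratio of major to
#'   minor ellipse axis (1 = circle).
#' @param cell_intensity_range Length-2 numeric in \[0, 1\], per-cell peak
#'   intensity sampled uniformly.
#' @param background_intensity Background level in \[0, 1\].
#' @param background_texture Standard deviation of the smooth background
#'   intensity field (0 disables texture).
#' @param noise_sigma Standard deviation of additive pixel noise.
#' @param overlap_fraction Fraction of cells placed touching an existing
#'   cell (centre distance `r1 + r2 - touch_delta`).
#' @param touch_delta Overlap depth in pixels for touching cells.
#' @param polarity `"bright"` for bright cells on a dark background,
#'   `"dark"` for the inverse.
#' @param seed Integer seed; identical seeds give bit-identical scenes.
#' @return An object of class `scene_spec`.
#' @examples
#' spec <- scene_spec(n_cells = 5, seed = 1)
#' scene <- generate_scene(spec)
#' nrow(scene$dots)
#' @export
scene_spec <- function(image_height = 128L, image_width = 128L, n_cells = 28L,
                       radius_range = c(4, 7), eccentricity_range = c(1, 1.8),
                       cell_intensity_range = c(0.7, 0.95),
                       background_intensity = 0.2, background_texture = 0.04,
                       noise_sigma = 0.03, overlap_fraction = 0.2,
                       touch_delta = 1, polarity = c("bright", "dark"),
                       seed = 1L) {
  polarity <- match.arg(polarity)
  if (image_height < 8 || image_width < 8) stopf("image must be at least 8x8")
  if (n_cells < 0) stopf("n_cells must be >= 0")
  if (length(radius_range) != 2 || radius_range[1] < 2)
    stopf("radius_range[1] must be >= 2 px")
  if (diff(radius_range) < 0 || diff(eccentricity_range) < 0)
    stopf("ranges must be non-decreasing")
  if (eccentricity_range[1] < 1) stopf("eccentricity must be >= 1")
  ints <- c(cell_intensity_range, background_intensity)
  if (any(ints < 0 | ints > 1))
    stopf("intensity parameters must lie in [0, 1]")
  if (noise_sigma < 0 || background_texture < 0)
    stopf("noise_sigma and background_texture must be >= 0")
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must lie in [0, 1]")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width), n_cells = as.integer(n_cells),
    radius_range = as.numeric(radius_range),
    eccentricity_range = as.numeric(eccentricity_range),
    cell_intensity_range = as.numeric(cell_intensity_range),
    background_intensity = background_intensity,
    background_texture = background_texture, noise_sigma = noise_sigma,
    overlap_fraction = overlap_fraction, touch_delta = touch_delta,
    polarity = polarity, seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Generate a synthetic scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: cells are rotated
#' ellipses with radial Fourier boundary jitter, composited by normalized
#' elliptical radius (a contested pixel belongs to the cell whose boundary it
#' is deepest inside), lightly smoothed, and degraded with Gaussian noise.
#' Every cell centre is recorded as a dot annotation and every cell as a
#' label in the instance mask, so dot containment holds by construction.
#'
#' @param spec A [scene_spec()].
#' @return An object of class `scene`: a list with `image` (numeric matrix in
#'   \[0, 1\]), `mask` (integer label matrix, background 0), `dots`
#'   (data.frame with zero-based `row`, `col` cell centres), and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  H <- spec$image_height; W <- spec$image_width
  with_seed(spec$seed, {
    n <- spec$n_cells
    rr <- spec$radius_range
    radius <- runif(n, rr[1], rr[2])
    ecc <- runif(n, spec$eccentricity_range[1], spec$eccentricity_range[2])
    orient <- runif(n, 0, pi)
    intensity <- runif(n, spec$cell_intensity_range[1],
                       spec$cell_intensity_range[2])
    jit_amp <- matrix(runif(3 * max(n, 1), 0, 0.06), ncol = 3)
    jit_ph <- matrix(runif(3 * max(n, 1), 0, 2 * pi), ncol = 3)

    centers <- matrix(NA_real_, n, 2)  # zero-based (row, col)
    n_touch <- if (n >= 2) round(spec$overlap_fraction * n) else 0L
    place_margin <- function(r) {
      lo <- ceiling(r) + 1; hi_r <- H - 2 - ceiling(r); hi_c <- W - 2 - ceiling(r)
      if (hi_r < lo || hi_c < lo) stopf("cells of radius %.1f do not fit the image", r)
      c(lo, hi_r, hi_c)
    }
    for (i in seq_len(n)) {
      touching <- i > (n - n_touch) && i > 1
      placed <- FALSE
      m <- place_margin(radius[i])
      for (try in seq_len(500L)) {
        if (touching) {
          a <- sample.int(i - 1L, 1L)
          th <- runif(1, 0, 2 * pi)
          d <- radius[i] + radius[a] - spec$touch_delta
          cand <- centers[a, ] + d * c(cos(th), sin(th))
        } else {
          cand <- c(runif(1, m[1], m[2]), runif(1, m[1], m[3]))
        }
        cand <- round(cand)
        if (cand[1] < m[1] || cand[1] > m[2] || cand[2] < m[1] || cand[2] > m[3]) next
        ok <- TRUE
        if (i > 1) {
          d2 <- sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                                matrix(cand, i - 1, 2, byrow = TRUE))^2))
          lim <- radius[seq_len(i - 1)] + radius[i] +
            ifelse(rep(touching, i - 1), -spec$touch_delta - 0.5, 2)
          if (touching) {
            lim[a] <- -Inf  # the anchor is allowed at touching distance
            if (d2[a] < radius[i]) ok <- FALSE  # but not engulfing its centre
          }
          if (any(d2 < lim)) ok <- FALSE
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed)
        stopf("could not place cell %d after 500 attempts; n_cells too large for the image", i)
    }

    img <- matrix(spec$background_intensity, H, W)
    if (spec$background_texture > 0) {
      tex <- gaussian_blur(matrix(rnorm(H * W), H, W), 6)
      img <- img + tex / stats::sd(tex) * spec$background_texture
    }
    mask <- matrix(0L, H, W)
    normrad <- matrix(Inf, H, W)
    for (i in seq_len(n)) {
      a <- radius[i] * sqrt(ecc[i]); b <- radius[i] / sqrt(ecc[i])
      r0 <- centers[i, 1]; c0 <- centers[i, 2]
      rad <- ceiling(a * 1.2) + 1
      rows <- max(0, r0 - rad):min(H - 1, r0 + rad)
      cols <- max(0, c0 - rad):min(W - 1, c0 + rad)
      dy <- matrix(rows - r0, length(rows), length(cols))
      dx <- matrix(cols - c0, length(rows), length(cols), byrow = TRUE)
      co <- cos(orient[i]); si <- sin(orient[i])
      u <- dy * co + dx * si
      v <- -dy * si + dx * co
      rho <- sqrt((u / a)^2 + (v / b)^2)
      psi <- atan2(v, u)
      jit <- 1
      for (k in 1:3) jit <- jit + jit_amp[i, k] * cos((k + 1) * psi + jit_ph[i, k])
      nr <- rho / jit
      sub <- cbind(rep(rows, length(cols)) + 1L,
                   rep(cols, each = length(rows)) + 1L)
      inside <- nr <= 1 & nr < normrad[sub]
      if (any(inside)) {
        sel <- sub[inside, , drop = FALSE]
        mask[sel] <- i
        normrad[sel] <- nr[inside]
        img[sel] <- intensity[i] * (1 - 0.15 * nr[inside]^2)
      }
    }
    img <- gaussian_blur(img, 0.7)
    if (spec$noise_sigma > 0) img <- img + rnorm(H * W) * spec$noise_sigma
    img <- pmin(pmax(img, 0), 1)
    if (spec$polarity == "dark") img <- 1 - img

    dots <- if (n > 0) {
      data.frame(row = as.integer(centers[, 1]), col = as.integer(centers[, 2]))
    } else {
      data.frame(row = integer(0), col = integer(0))
    }
    structure(list(image = img, mask = mask, dots = dots, spec = spec),
              class = "scene")
  })
}

#' Easy-contrast scene preset
#'
#' A homogeneous, high-contrast cell population: narrow size and intensity
#' ranges, mild eccentricity, low noise, and few touching pairs, on a
#' larger field. This emulates the benign end of fluorescence benchmarks
#' (uniform stained cells on a dark background) and is the default
#' condition of the detection benchmark; the plain [scene_spec()] defaults
#' describe a more heterogeneous population.
#'
#' @param ... Overrides passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
scene_spec_easy <- function(...) {
  args <- list(image_height = 192L, image_width = 192L, n_cells = 60L,
               radius_range = c(4.5, 6), eccentricity_range = c(1, 1.3),
               cell_intensity_range = c(0.8, 0.9), noise_sigma = 0.02,
               overlap_fraction = 0.1, background_texture = 0.03)
  over <- list(...)
  for (k in names(over)) args[[k]] <- over[[k]]
  do.call(scene_spec, args)
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("synthetic scene: %dx%d px, %d cells, polarity %s, seed %d\n",
              nrow(x$image), ncol(x$image), nrow(x$dots),
              x$spec$polarity, x$spec$seed))
  invisible(x)
}

#' Write a scene to disk
#'
#' Writes the image as a 16-bit grayscale TIFF, the instance mask as a 16-bit
#' label TIFF, the dot annotations as a CSV with columns `image,row,col`
#' (zero-based coordinates), and a JSON manifest listing the files.
#'
#' @param scene A `scene` from [generate_scene()].
#' @param dir Output directory (created if missing).
#' @param name Basename and image id used for the files.
#' @return Invisibly, the manifest as a named list.
#' @export
write_scene <- function(scene, dir, name = "scene") {
  stopifnot(inherits(scene, "scene"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", dir)
  paths <- file.path(dir, paste0(name, c("_image.tif", "_mask.tif",
                                         "_dots.csv", "_manifest.json")))
  if (max(scene$mask) > 65535L) stopf("more than 65535 instances; mask does not fit 16 bits")
  ok1 <- tiff::writeTIFF(pmin(pmax(scene$image, 0), 1), paths[1],
                         bits.per.sample = 16L)
  ok2 <- tiff::writeTIFF(scene$mask / 65535, paths[2], bits.per.sample = 16L)
  if (!isTRUE(ok1 == 1L) || !isTRUE(ok2 == 1L))
    stopf("failed to write TIFF files under '%s'", dir)
  dots <- cbind(image = rep(name, nrow(scene$dots)), scene$dots)
  if (nrow(scene$dots) == 0)
    dots <- data.frame(image = character(0), row = integer(0), col = integer(0))
  write.csv(dots, paths[3], row.names = FALSE, quote = FALSE)
  manifest <- list(image = basename(paths[1]), mask = basename(paths[2]),
                   dots = basename(paths[3]), name = name,
                   n_cells = nrow(scene$dots),
                   height = nrow(scene$image), width = ncol(scene$image))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Read a scene back from disk
#'
#' Counterpart of [write_scene()]; reconstructs image, integer mask, and
#' dots from a manifest.
#'
#' @param dir Directory written by [write_scene()].
#' @param name Basename used when writing.
#' @return A list with `image`, `mask`, and `dots`.
#' @export
read_scene <- function(dir, name = "scene") {
  mf <- file.path(dir, paste0(name, "_manifest.json"))
  if (!file.exists(mf)) stopf("manifest '%s' not found", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  image <- tiff::readTIFF(file.path(dir, manifest$image))
  mask_raw <- tiff::readTIFF(file.path(dir, manifest$mask))
  mask <- matrix(as.integer(round(mask_raw * 65535)), nrow(mask_raw), ncol(mask_raw))
  dots <- read.csv(file.path(dir, manifest$dots))
  list(image = image, mask = mask, dots = dots[, c("row", "col"), drop = FALSE],
       name = manifest$name)
}

#' Read dot annotations from CSV
#'
#' @param path CSV with columns `image,row,col`, zero-based coordinates.
#' @param image Optional image id filter.
#' @return data.frame with columns `image`, `row`, `col`.
#' @export
read_dots <- function(path, image = NULL) {
  d <- read.csv(path)
  need <- c("image", "row", "col")
  if (!all(need %in% names(d))) stopf("dots CSV must have columns image,row,col")
  if (!is.null(image)) d <- d[d$image == image, , drop = FALSE]
  d[, need, drop = FALSE]
}
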