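#' Induce region labels from dot annotations
#'
#' A region is a positive training example if and only if it contains
#' exactly one dot and is the largest such region on its path, i.e. its
#' parent (when it has one) contains a different number of dots. Because dot
#' counts are non-decreasing from leaf to root, at most one region per
#' root-to-leaf path can be positive, so the labels themselves satisfy the
#' path-consistency constraint. Dots falling outside every candidate region
#' yield no positive and are silently skipped: candidate-generation recall
#' is not the supervision stage's concern.
#'
#' @param forest A [build_forest()] result.
#' @param dots data.frame with zero-based `row`, `col` (same image).
#' @return Integer vector of 0/1 labels, one per region.
#' @export
induce_region_labels <- function(forest, dots) {
  stopifnot(inherits(forest, "region_forest"))
  n <- nrow(forest$nodes)
  if (n == 0) return(integer(0))
  H <- forest$dim[1]
  dot_idx <- if (nrow(dots)) rc_to_index(dots$row, dots$col, H) else integer(0)
  counts <- vapply(forest$pixels, function(p) sum(dot_idx %in% p), integer(1))
  par <- forest$nodes$parent
  par_counts <- ifelse(is.na(par), -1L, counts[ifelse(is.na(par), 1L, par)])
  as.integer(counts == 1L & par_counts != 1L)
}

#' Build a pool of annotated subimages
#'
#' Crops of roughly `crop_fraction` of the source image area (side
#' `sqrt(crop_fraction) * min(H, W)`), each centred on a dot and clipped to
#' the image, so every crop contains at least one annotated cell. A training
#' run draws a few crops from this pool; the pool itself is deterministic
#' under the seed.
#'
#' @param scenes List of lists with elements `image` (matrix) and `dots`
#'   (zero-based data.frame); [generate_scene()] output qualifies.
#' @param crop_fraction Crop area as a fraction of the image area.
#' @param seed Seed fixing the pool order.
#' @return Object of class `subimage_pool`: data.frame of crops with
#'   `image_idx`, `row0`, `row1`, `col0`, `col1` (zero-based, inclusive)
#'   plus the source scenes.
#' @export
make_subimage_pool <- function(scenes, crop_fraction = 1 / 8, seed = 1L) {
  stopifnot(length(scenes) >= 1, crop_fraction > 0, crop_fraction <= 1)
  crops <- list()
  with_seed(seed, {
    for (si in seq_along(scenes)) {
      img <- scenes[[si]]$image
      dots <- scenes[[si]]$dots
      if (nrow(dots) == 0) next
      H <- nrow(img); W <- ncol(img)
      side <- max(8L, round(sqrt(crop_fraction) * min(H, W)))
      ord <- sample.int(nrow(dots))
      for (d in ord) {
        r0 <- min(max(dots$row[d] - side %/% 2, 0L), H - side)
        c0 <- min(max(dots$col[d] - side %/% 2, 0L), W - side)
        crops[[length(crops) + 1L]] <- data.frame(
          image_idx = si, row0 = r0, row1 = r0 + side - 1L,
          col0 = c0, col1 = c0 + side - 1L)
      }
    }
  })
  if (length(crops) == 0)
    stopf("no crop contains a dot; are the scenes annotated?")
  structure(list(crops = do.call(rbind, crops), scenes = scenes,
                 crop_fraction = crop_fraction), class = "subimage_pool")
}

#' Draw labeled crops from a pool
#'
#' Randomly selects `k` crops (mirroring repeated experiments with random
#' subimage draws) and extracts each crop's image and the dots whose centre
#' lies inside it, re-expressed in crop coordinates.
#'
#' @param pool A [make_subimage_pool()] result.
#' @param k Number of crops.
#' @param seed Draw seed.
#' @return List of length `k`; each element has `image`, `dots`, and the
#'   crop window.
#' @export
sample_crops <- function(pool, k, seed = 1L) {
  stopifnot(inherits(pool, "subimage_pool"))
  n <- nrow(pool$crops)
  if (k > n) stopf("requested %d crops but the pool has %d", k, n)
  sel <- with_seed(seed, sample.int(n, k))
  lapply(sel, function(i) {
    cr <- pool$crops[i, ]
    sc <- pool$scenes[[cr$image_idx]]
    img <- sc$image[(cr$row0:cr$row1) + 1L, (cr$col0:cr$col1) + 1L]
    keep <- sc$dots$row >= cr$row0 & sc$dots$row <= cr$row1 &
      sc$dots$col >= cr$col0 & sc$dots$col <= cr$col1
    dots <- data.frame(row = sc$dots$row[keep] - cr$row0,
                       col = sc$dots$col[keep] - cr$col0)
    list(image = img, dots = dots, window = cr, source_dim = dim(sc$image))
  })
}

#' Window-restricted supervision on a full-image forest
#'
#' Training annotations live in subimage windows, but candidate regions are
#' generated on the full image; supervision therefore applies to the
#' regions that lie entirely inside an annotated window, labeled by the
#' same largest-single-dot rule as [induce_region_labels()] restricted to
#' the window's dots and to window-contained ancestors. This keeps the
#' supervised feature rows identical to rows of the unsupervised feature
#' matrix, so the supervised loss anchors specific nodes of the very trees
#' the path-consistency loss operates on.
#'
#' @param forest A [build_forest()] result for the full image.
#' @param dots Zero-based dot coordinates in full-image coordinates (only
#'   those inside the window are used).
#' @param window List or one-row data.frame with `row0`, `row1`, `col0`,
#'   `col1` (zero-based, inclusive).
#' @return List with `ids` (region ids inside the window) and `labels`
#'   (0/1 per id).
#' @export
window_supervision <- function(forest, dots, window) {
  stopifnot(inherits(forest, "region_forest"))
  H <- forest$dim[1]
  n <- nrow(forest$nodes)
  if (n == 0) return(list(ids = integer(0), labels = integer(0)))
  contained <- vapply(forest$pixels, function(p) {
    rc <- index_to_rc(p, H)
    all(rc$row >= window$row0 & rc$row <= window$row1 &
          rc$col >= window$col0 & rc$col <= window$col1)
  }, logical(1))
  ids <- which(contained)
  if (length(ids) == 0) return(list(ids = integer(0), labels = integer(0)))
  keep <- dots$row >= window$row0 & dots$row <= window$row1 &
    dots$col >= window$col0 & dots$col <= window$col1
  dot_idx <- if (any(keep)) rc_to_index(dots$row[keep], dots$col[keep], H) else integer(0)
  counts <- vapply(forest$pixels, function(p) sum(dot_idx %in% p), integer(1))
  # nearest window-contained ancestor
  anc_count <- vapply(ids, function(i) {
    p <- forest$nodes$parent[i]
    while (!is.na(p) && !contained[p]) p <- forest$nodes$parent[p]
    if (is.na(p)) -1L else counts[p]
  }, integer(1))
  labels <- as.integer(counts[ids] == 1L & anc_count != 1L)
  list(ids = ids, labels = labels)
}

#' Write induced labels to CSV
#'
#' @param labels Integer label vector from [induce_region_labels()].
#' @param image Image id.
#' @param path Output CSV (`image,region_id,label`).
#' @return Invisibly, `path`.
#' @export
write_region_labels <- function(labels, image, path) {
  write.csv(data.frame(image = image, region_id = seq_along(labels),
                       label = labels), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
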