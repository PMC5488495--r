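#' Build the forest of nested extremal regions
#'
#' Computes the component (max-) tree of a quantized image or probability
#' map: for every threshold level, the connected components (4-connectivity)
#' of the super-level set are candidate regions, and nesting across levels
#' defines parent/child links. Components whose pixel set is identical
#' across adjacent levels appear as a single node. Nodes are then filtered
#' to the configured area range; each surviving node is linked to its
#' nearest surviving ancestor, so the result is a forest whose trees cover
#' the connected components of the (filtered) foreground.
#'
#' With a finite `max_variation` the forest is additionally restricted to
#' maximally stable extremal regions: a node's variation is its relative
#' area growth towards the ancestor `stability_delta` levels below, and a
#' node is kept only when its variation is a local minimum along its chain
#' (no larger than its parent's or any child's) and below the threshold.
#' This collapses the long runs of near-identical nested regions that a
#' smooth-edged object produces across thresholds to the few sharpest
#' candidates, which is the detector's working representation; the default
#' `max_variation = Inf` retains the complete tree instead.
#'
#' @param map Numeric matrix: intensity image or probability map. Values are
#'   rescaled to \[0, 1\] and quantized to `n_levels` gray levels.
#' @param min_area,max_area Retained region area bounds in pixels.
#'   `max_area = NULL` defaults to 1% of the image area.
#' @param polarity `"bright"` detects bright-on-dark regions; `"dark"`
#'   inverts the map first.
#' @param n_levels Number of quantization levels (default 256).
#' @param max_variation Variation threshold of the stability filter;
#'   `Inf` (default) disables it and keeps the complete tree. The detector
#'   uses a lenient threshold of 1 so that all plausible cell candidates
#'   survive.
#' @param stability_delta Level offset used by the stability filter.
#' @param min_diversity With the stability filter active, nested kept
#'   regions whose areas differ by less than this fraction (of the larger)
#'   are deduplicated, keeping the more stable one -- the diversity
#'   criterion of standard MSER detectors.
#' @return An object of class `region_forest`: list with `nodes`
#'   (data.frame `id`, `parent` (NA for roots), `level`, `area`), `pixels`
#'   (list of 1-based linear pixel indices, column-major, full nested pixel
#'   set per node), and `dim`.
#' @examples
#' img <- matrix(0, 32, 32); img[5:10, 5:10] <- 1; img[20:26, 18:25] <- 0.8
#' f <- build_forest(img, min_area = 10)
#' nrow(f$nodes)
#' @export
build_forest <- function(map, min_area = 30L, max_area = NULL,
                         polarity = c("bright", "dark"), n_levels = 256L,
                         max_variation = Inf, stability_delta = 5L,
                         min_diversity = 0.2) {
  check_image(map, "map")
  polarity <- match.arg(polarity)
  if (is.null(max_area)) max_area <- max(min_area, ceiling(0.01 * length(map)))
  if (min_area < 1) stopf("min_area must be >= 1")
  if (min_area > max_area) stopf("min_area (%d) exceeds max_area (%d)",
                                 min_area, max_area)
  H <- nrow(map); W <- ncol(map)
  rng <- range(map)
  q <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
  if (polarity == "dark") q <- 1 - q
  qi <- matrix(as.integer(round(q * (n_levels - 1L))), H, W)

  mt <- maxtree_build(qi)
  parent_px <- mt$parent + 1L  # 1-based pixel parents
  val <- mt$value

  # Canonical element per pixel: itself if it represents a node, else its
  # (canonical) parent.
  is_canon <- parent_px == seq_along(parent_px) |
    val != val[parent_px]
  canon <- ifelse(is_canon, seq_along(parent_px), parent_px)

  reps <- which(is_canon)
  node_of_px <- match(canon, reps)               # node id per pixel
  n_nodes <- length(reps)
  level <- val[reps]
  par_node <- node_of_px[parent_px[reps]]
  par_node[par_node == seq_len(n_nodes)] <- NA_integer_  # roots

  # Full (nested) pixel sets: accumulate children into parents in
  # decreasing-level order, at which point each child's set is complete.
  own <- split(seq_along(node_of_px), node_of_px)
  pix <- vector("list", n_nodes)
  pix[as.integer(names(own))] <- own
  ord <- order(level, decreasing = TRUE)
  for (i in ord) {
    p <- par_node[i]
    if (!is.na(p)) pix[[p]] <- c(pix[[p]], pix[[i]])
  }
  area <- lengths(pix)

  keep <- area >= min_area & area <= max_area
  if (is.finite(max_variation)) {
    # MSER-style stability selection: the variation of a node is the
    # relative area growth towards its ancestor `stability_delta` levels
    # below; a region is maximally stable when its variation does not
    # exceed that of its parent or of any child, and is below the (lenient)
    # variation threshold.
    # Area of the component at level (own level - delta). Each collapsed
    # node spans the level interval (parent level, own level]; when that
    # interval already contains the target level the component is the node
    # itself (variation 0 across its plateau), otherwise walk up to the
    # ancestor whose interval contains it.
    anc_area <- vapply(seq_len(n_nodes), function(i) {
      target <- level[i] - stability_delta
      j <- i
      while (!is.na(par_node[j]) && level[par_node[j]] >= target)
        j <- par_node[j]
      area[j]
    }, numeric(1))
    v <- (anc_area - area) / area
    stable <- v <= max_variation
    for (i in seq_len(n_nodes)) {
      p <- par_node[i]
      if (!is.na(p) && v[i] > v[p]) stable[i] <- FALSE
      if (!is.na(p) && v[p] > v[i]) stable[p] <- FALSE
    }
    keep <- keep & stable
    if (min_diversity > 0) {
      # Diversity pruning (as in standard MSER detectors): of two nested
      # kept regions whose areas differ by less than min_diversity
      # (relative to the larger), keep only the more stable one.
      repeat {
        changed <- FALSE
        for (i in order(area)) {
          if (!keep[i]) next
          p <- par_node[i]
          while (!is.na(p) && !keep[p]) p <- par_node[p]
          if (is.na(p)) next
          if ((area[p] - area[i]) / area[p] < min_diversity) {
            # keep the more stable region; on ties prefer the larger one
            drop <- if (v[p] <= v[i]) i else p
            keep[drop] <- FALSE
            changed <- TRUE
          }
        }
        if (!changed) break
      }
    }
  }
  kept <- which(keep)
  if (length(kept) == 0) {
    return(structure(list(
      nodes = data.frame(id = integer(0), parent = integer(0),
                         level = integer(0), area = integer(0)),
      pixels = list(), dim = c(H, W), n_levels = n_levels,
      polarity = polarity), class = "region_forest"))
  }
  new_id <- match(seq_len(n_nodes), kept)
  nearest_kept_ancestor <- function(i) {
    p <- par_node[i]
    while (!is.na(p) && !keep[p]) p <- par_node[p]
    if (is.na(p)) NA_integer_ else new_id[p]
  }
  nodes <- data.frame(
    id = seq_along(kept),
    parent = vapply(kept, nearest_kept_ancestor, integer(1)),
    level = level[kept], area = as.integer(area[kept]))
  structure(list(nodes = nodes,
                 pixels = lapply(pix[kept], function(p) sort(as.integer(p))),
                 dim = c(H, W), n_levels = n_levels, polarity = polarity),
            class = "region_forest")
}

#' @export
print.region_forest <- function(x, ...) {
  cat(sprintf("region forest: %d regions, %d trees, image %dx%d\n",
              nrow(x$nodes), sum(is.na(x$nodes$parent)), x$dim[1], x$dim[2]))
  invisible(x)
}

# children lists, index = node id
forest_children <- function(forest) {
  n <- nrow(forest$nodes)
  ch <- vector("list", n)
  par <- forest$nodes$parent
  for (i in seq_len(n)) {
    p <- par[i]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

forest_roots <- function(forest) which(is.na(forest$nodes$parent))

#' Enumerate all root-to-leaf paths
#'
#' Every leaf of every tree in the forest yields exactly one path, listed in
#' root-to-leaf order. Paths are the domain of the path-consistency loss:
#' along each path the regions are nested, so at most one of them may be a
#' cell.
#'
#' @param forest A [build_forest()] result.
#' @return A list of integer vectors of region ids (class `path_set`).
#' @export
enumerate_paths <- function(forest) {
  stopifnot(inherits(forest, "region_forest"))
  ch <- forest_children(forest)
  paths <- list()
  for (r in forest_roots(forest)) {
    stack <- list(r)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      node <- p[length(p)]
      kids <- ch[[node]]
      if (length(kids) == 0) {
        paths[[length(paths) + 1L]] <- p
      } else {
        for (k in rev(kids)) stack[[length(stack) + 1L]] <- c(p, k)
      }
    }
  }
  structure(paths, class = "path_set")
}

#' Descendants of a region
#'
#' Transitive closure of the child relation.
#'
#' @param forest A [build_forest()] result.
#' @param id Region id.
#' @return Integer vector of descendant ids (empty for leaves).
#' @export
descendants <- function(forest, id) {
  stopifnot(inherits(forest, "region_forest"))
  n <- nrow(forest$nodes)
  if (length(id) != 1 || is.na(id) || id < 1 || id > n)
    stopf("unknown region id")
  ch <- forest_children(forest)
  out <- integer(0)
  queue <- ch[[id]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(ch[queue])
  }
  sort(out)
}

#' Serialize a forest to JSON
#'
#' Writes node table plus run-length-encoded pixel sets, readable with
#' [read_forest()].
#'
#' @param forest A `region_forest`.
#' @param path Output JSON file.
#' @return Invisibly, `path`.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "region_forest"))
  rle_enc <- function(p) {
    if (length(p) == 0) return(list(start = integer(0), len = integer(0)))
    brk <- c(TRUE, diff(p) != 1L)
    list(start = p[brk], len = as.integer(diff(c(which(brk), length(p) + 1L))))
  }
  obj <- list(dim = forest$dim, n_levels = forest$n_levels,
              polarity = forest$polarity, nodes = forest$nodes,
              pixels = lapply(forest$pixels, rle_enc))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a forest written by [write_forest()]
#' @param path JSON file.
#' @return A `region_forest`.
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path)
  col <- function(nm) vapply(obj$nodes, function(n)
    if (is.null(n[[nm]])) NA_integer_ else as.integer(n[[nm]]), integer(1))
  nodes <- data.frame(id = col("id"), parent = col("parent"),
                      level = col("level"), area = col("area"))
  pix <- lapply(obj$pixels, function(e) {
    starts <- as.integer(unlist(e$start))
    lens <- as.integer(unlist(e$len))
    if (length(starts) == 0) return(integer(0))
    as.integer(unlist(mapply(function(s, l) seq.int(s, length.out = l),
                             starts, lens, SIMPLIFY = FALSE)))
  })
  structure(list(nodes = nodes, pixels = pix,
                 dim = as.integer(unlist(obj$dim)),
                 n_levels = as.integer(obj$n_levels),
                 polarity = as.character(obj$polarity)),
            class = "region_forest")
}

#' Paint regions into a label image (for inspection)
#'
#' @param forest A `region_forest`.
#' @param ids Region ids to paint; later ids overwrite earlier ones.
#' @return Integer label matrix of the forest's image size.
#' @export
region_label_image <- function(forest, ids = seq_len(nrow(forest$nodes))) {
  lab <- matrix(0L, forest$dim[1], forest$dim[2])
  for (i in seq_along(ids)) lab[forest$pixels[[ids[i]]]] <- i
  lab
}
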