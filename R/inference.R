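#' Greedy per-path inference
#'
#' For each root-to-leaf path, selects the highest-scoring node and labels
#' the rest 0. Cross-path conflicts are resolved by processing paths in
#' descending order of their best score: nodes already forced to 0 by an
#' earlier selection (ancestors or descendants of a selected node) are
#' skipped and the path falls back to its best still-admissible node; a
#' path that already contains a selected node is left alone. The output
#' always satisfies the non-overlap constraint.
#'
#' @param forest A [build_forest()] result.
#' @param scores Per-region scores in (0, 1).
#' @return Object of class `detections` (see [top_down_labels()]).
#' @export
greedy_infer <- function(forest, scores) {
  stopifnot(inherits(forest, "region_forest"),
            length(scores) == nrow(forest$nodes))
  n <- nrow(forest$nodes)
  paths <- enumerate_paths(forest)
  y <- integer(n)
  forbidden <- logical(n)
  if (length(paths) > 0) {
    ord <- order(vapply(paths, function(p) max(scores[p]), numeric(1)),
                 decreasing = TRUE)
    for (p in paths[ord]) {
      if (any(y[p] == 1L)) next
      cand <- p[!forbidden[p]]
      if (length(cand) == 0) next
      pick <- cand[which.max(scores[cand])]
      y[pick] <- 1L
      anc <- integer(0)
      a <- forest$nodes$parent[pick]
      while (!is.na(a)) { anc <- c(anc, a); a <- forest$nodes$parent[a] }
      forbidden[c(pick, anc, descendants(forest, pick))] <- TRUE
    }
  }
  make_detections(forest, y, scores, method = "greedy")
}

#' Bottom-up energy computation
#'
#' For every node, the selected energy is the cost of labelling the node 1
#' and all of its descendants 0:
#' `E_s(i) = -log f_i + sum_{k in desc(i)} -log(1 - f_k)`; the not-selected
#' energy labels the node 0 and its children optimally:
#' `E_ns(i) = -log(1 - f_i) + sum_{c in children(i)} min(E_s(c), E_ns(c))`
#' (the sum runs over however many children the node has). Leaves reduce to
#' `-log f_i` and `-log(1 - f_i)`. Scores are clipped to
#' `[1e-6, 1 - 1e-6]` before taking logarithms.
#'
#' @param forest A [build_forest()] result.
#' @param scores Per-region scores.
#' @return List with vectors `E_s` and `E_ns`.
#' @export
bottom_up_energies <- function(forest, scores) {
  stopifnot(inherits(forest, "region_forest"),
            length(scores) == nrow(forest$nodes))
  f <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  n <- nrow(forest$nodes)
  ch <- forest_children(forest)
  E_s <- numeric(n); E_ns <- numeric(n)
  S <- numeric(n)  # sum of -log(1 - f) over the node and its descendants
  ord <- order(forest$nodes$level, decreasing = TRUE)  # children first
  for (i in ord) {
    kids <- ch[[i]]
    sum_S <- sum(S[kids])
    S[i] <- -log(1 - f[i]) + sum_S
    E_s[i] <- -log(f[i]) + sum_S
    E_ns[i] <- -log(1 - f[i]) + sum(pmin(E_s[kids], E_ns[kids]))
  }
  list(E_s = E_s, E_ns = E_ns)
}

#' Top-down label assignment
#'
#' Starting from each root, a node is selected when its selected energy is
#' strictly lower than its not-selected energy (ties prefer descending into
#' the subtrees, which favours finer regions); selecting a node stops the
#' recursion so all its descendants stay 0. The resulting labels minimize
#' the total detection energy subject to the at-most-one-per-path
#' constraint.
#'
#' @param forest A [build_forest()] result.
#' @param energies Result of [bottom_up_energies()].
#' @param scores Scores used for the energies (stored with the output).
#' @return Object of class `detections`: list with `y` (0/1 per region),
#'   `selected` ids, `centroids` (zero-based data.frame), `energy`, and the
#'   inference method.
#' @export
top_down_labels <- function(forest, energies, scores = NULL) {
  stopifnot(inherits(forest, "region_forest"))
  n <- nrow(forest$nodes)
  ch <- forest_children(forest)
  y <- integer(n)
  queue <- forest_roots(forest)
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (energies$E_s[i] < energies$E_ns[i]) {
      y[i] <- 1L
    } else {
      queue <- c(queue, ch[[i]])
    }
  }
  make_detections(forest, y, scores, method = "dp")
}

make_detections <- function(forest, y, scores = NULL, method = "dp") {
  sel <- which(y == 1L)
  H <- forest$dim[1]
  cent <- if (length(sel)) {
    do.call(rbind, lapply(sel, function(i) {
      rc <- index_to_rc(forest$pixels[[i]], H)
      data.frame(region_id = i, row = mean(rc$row), col = mean(rc$col))
    }))
  } else {
    data.frame(region_id = integer(0), row = numeric(0), col = numeric(0))
  }
  energy <- if (!is.null(scores)) {
    f <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
    -sum(y * log(f) + (1 - y) * log(1 - f))
  } else NA_real_
  structure(list(y = y, selected = sel, centroids = cent, energy = energy,
                 method = method, dim = forest$dim),
            class = "detections")
}

#' @export
print.detections <- function(x, ...) {
  cat(sprintf("detections: %d regions selected (%s inference)\n",
              length(x$selected), x$method))
  invisible(x)
}

#' Detection energy of a labelling
#'
#' The constrained objective value `sum_i -y_i log f_i - (1 - y_i)
#' log(1 - f_i)`, with the same score clipping as the dynamic program.
#'
#' @param y Binary labels per region.
#' @param scores Per-region scores.
#' @return Scalar energy.
#' @export
detection_energy <- function(y, scores) {
  f <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  -sum(y * log(f) + (1 - y) * log(1 - f))
}

#' Check the non-overlap constraint
#'
#' @param forest A `region_forest`.
#' @param y Binary labels per region.
#' @return `TRUE` if no selected region has a selected descendant.
#' @export
satisfies_path_constraint <- function(forest, y) {
  for (i in which(y == 1L)) {
    if (any(y[descendants(forest, i)] == 1L)) return(FALSE)
  }
  TRUE
}

#' End-to-end detection on one image
#'
#' Builds the region forest (on the image itself or on a probability map
#' produced by a pixel model), extracts and standardizes features, scores
#' regions with the trained classifier, and selects non-overlapping
#' detections by dynamic programming (or greedily).
#'
#' @param image Image matrix in \[0, 1\].
#' @param checkpoint A trained detector checkpoint from [train_detector()]
#'   (model, standardizer, and stage parameters).
#' @param pixel_model Optional [train_pixel_classifier()] model; when given,
#'   the forest is built on its probability map.
#' @param method `"dp"` (default) or `"greedy"`.
#' @return A `detections` object with the forest and scores attached.
#' @export
detect_cells <- function(image, checkpoint, pixel_model = NULL,
                         method = c("dp", "greedy")) {
  method <- match.arg(method)
  if (!inherits(checkpoint, "detector_checkpoint"))
    stopf("a trained detector checkpoint is required")
  map <- if (is.null(pixel_model)) image else
    predict_probability_map(pixel_model, image)
  tp <- checkpoint$tree_params
  forest <- build_forest(map, min_area = tp$min_area, max_area = tp$max_area,
                         polarity = tp$polarity, n_levels = tp$n_levels,
                         max_variation = tp$max_variation %||% Inf,
                         stability_delta = tp$stability_delta %||% 5L,
                         min_diversity = tp$min_diversity %||% 0.2)
  X <- region_features(forest, image, checkpoint$feature_config)
  if (nrow(X) == 0) {
    det <- make_detections(forest, integer(0), NULL, method)
  } else {
    Xs <- apply_standardizer(X, checkpoint$standardizer)
    scores <- score_region(checkpoint$model$params, Xs)
    det <- if (method == "greedy") greedy_infer(forest, scores) else
      top_down_labels(forest, bottom_up_energies(forest, scores), scores)
    det$scores <- scores
  }
  det$forest <- forest
  det
}

#' Write detections to CSV
#'
#' @param det A `detections` object.
#' @param image Image id.
#' @param path Output CSV (`image,region_id,row,col` centroids, zero-based).
#' @return Invisibly, `path`.
#' @export
write_detections <- function(det, image, path) {
  d <- det$centroids
  out <- if (nrow(d)) cbind(image = image, d) else
    data.frame(image = character(0), region_id = integer(0),
               row = numeric(0), col = numeric(0))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Label image of selected regions
#'
#' @param det A `detections` object with its forest attached.
#' @return Integer label matrix, one label per selected region.
#' @export
detection_mask <- function(det) {
  stopifnot(inherits(det, "detections"), !is.null(det$forest))
  region_label_image(det$forest, det$selected)
}
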