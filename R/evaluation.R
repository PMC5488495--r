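#' Match detections to ground truth by Hungarian assignment
#'
#' Finds the one-to-one assignment between ground-truth cell centres and
#' predicted centroids that minimizes the total centroid distance (solved
#' as a linear sum assignment problem), then discards pairs farther apart
#' than `max_distance`. When the predicted regions' pixel sets are supplied
#' and the ground truth is dots, a pair additionally requires the dot to
#' lie inside the predicted region. Matched pairs are true positives;
#' unmatched predictions are false positives and unmatched ground-truth
#' cells are false negatives.
#'
#' @param gt data.frame of ground-truth centres (zero-based `row`, `col`).
#' @param pred data.frame of predicted centroids (`row`, `col`).
#' @param max_distance Matching gate in pixels (default: the mean cell
#'   radius of the dataset is a sensible choice).
#' @param pred_pixels Optional list of pixel sets (1-based linear indices)
#'   parallel to `pred`, plus `H` giving the image height, to enforce
#'   dot-in-region containment.
#' @param H Image height (rows); required with `pred_pixels`.
#' @return Object of class `match_result` with `TP`, `FP`, `FN`, `pairs`,
#'   `precision`, `recall`, `f_score`.
#' @export
match_detections <- function(gt, pred, max_distance = Inf,
                             pred_pixels = NULL, H = NULL) {
  n_gt <- nrow(gt); n_pr <- nrow(pred)
  pairs <- data.frame(gt = integer(0), pred = integer(0), dist = numeric(0))
  if (n_gt > 0 && n_pr > 0) {
    cost <- outer(seq_len(n_gt), seq_len(n_pr), function(i, j) {
      sqrt((gt$row[i] - pred$row[j])^2 + (gt$col[i] - pred$col[j])^2)
    })
    admissible <- cost <= max_distance
    if (!is.null(pred_pixels)) {
      stopifnot(!is.null(H), length(pred_pixels) == n_pr)
      gt_idx <- rc_to_index(round(gt$row), round(gt$col), H)
      inside <- vapply(seq_len(n_pr), function(j) gt_idx %in% pred_pixels[[j]],
                       logical(n_gt))
      inside <- matrix(inside, n_gt, n_pr)
      admissible <- admissible & inside
    }
    big <- max(cost[is.finite(cost)], max_distance[is.finite(max_distance)], 1) *
      (n_gt + n_pr + 1)
    cost_g <- ifelse(admissible, cost, big)
    sol <- if (n_gt <= n_pr) {
      cbind(seq_len(n_gt), as.integer(clue::solve_LSAP(cost_g)))
    } else {
      cbind(as.integer(clue::solve_LSAP(t(cost_g))), seq_len(n_pr))
    }
    keep <- admissible[sol]
    if (any(keep)) {
      sol <- sol[keep, , drop = FALSE]
      pairs <- data.frame(gt = sol[, 1], pred = sol[, 2], dist = cost[sol])
    }
  }
  TP <- nrow(pairs); FP <- n_pr - TP; FN <- n_gt - TP
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  structure(list(TP = TP, FP = FP, FN = FN, pairs = pairs,
                 precision = precision, recall = recall, f_score = f),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d FN=%d  P=%.4f R=%.4f F=%.4f\n",
              x$TP, x$FP, x$FN, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' DICE coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)` over the binarized foregrounds (any nonzero
#' label is foreground). Two empty masks are defined to agree perfectly
#' (DICE 1).
#'
#' @param gt_mask,pred_mask Label or binary matrices of equal size.
#' @return Scalar in \[0, 1\].
#' @export
dice_score <- function(gt_mask, pred_mask) {
  stopifnot(all(dim(gt_mask) == dim(pred_mask)))
  a <- gt_mask > 0; b <- pred_mask > 0
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Evaluate detections on a set of scenes
#'
#' Runs [match_detections()] per scene against the ground-truth dots and
#' pools the counts into aggregate precision/recall/F (micro-average).
#'
#' @param detections List of `detections` objects.
#' @param scenes List of scenes (each with `dots`, optionally `mask`).
#' @param max_distance Matching gate in pixels.
#' @return List with per-scene results and pooled `precision`, `recall`,
#'   `f_score`, and mean `dice` (when masks are available).
#' @export
evaluate_detections <- function(detections, scenes, max_distance) {
  stopifnot(length(detections) == length(scenes))
  per <- vector("list", length(scenes))
  TP <- FP <- FN <- 0
  dice <- numeric(0)
  for (i in seq_along(scenes)) {
    det <- detections[[i]]
    m <- match_detections(scenes[[i]]$dots, det$centroids, max_distance,
                          pred_pixels = if (!is.null(det$forest))
                            det$forest$pixels[det$selected],
                          H = det$dim[1])
    per[[i]] <- m
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    if (!is.null(scenes[[i]]$mask) && !is.null(det$forest))
      dice <- c(dice, dice_score(scenes[[i]]$mask, detection_mask(det)))
  }
  precision <- if (TP + FP > 0) TP / (TP + FP) else 0
  recall <- if (TP + FN > 0) TP / (TP + FN) else 0
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(per_scene = per, TP = TP, FP = FP, FN = FN, precision = precision,
       recall = recall, f_score = f,
       dice = if (length(dice)) mean(dice) else NA_real_)
}
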