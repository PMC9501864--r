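#' Estimate anchor boxes by IoU k-means over box shapes
#'
#' Clusters training-box `(w, h)` pairs with the distance `1 - IoU` between a
#' box and an anchor placed at a common centre (so only shapes matter).
#' Initialisation is k-means++-style under a private seeded stream; centroid
#' updates are means of the member shapes, and the iteration stops (keeping
#' the previous centroids) as soon as an update would increase the mean
#' `1 - IoU` objective, so the objective never increases across iterations.
#'
#' Anchors are sorted by area and partitioned between the detector's two
#' heads: the larger half (rounded up) to the coarse head, the rest to the
#' fine head.
#'
#' @param boxes box data frame (only `w`, `h` are used).
#' @param k number of anchors (default 23).
#' @param seed seed for the initialisation.
#' @param max_iter Lloyd iteration cap.
#' @return An `anchor_set`: list with `anchors` (k x 2 matrix `w, h`, sorted
#'   by area), `fine`, `coarse` (the partition), and `mean_iou` (mean best
#'   anchor IoU over the input boxes).
#' @export
estimate_anchors <- function(boxes, k = 23, seed = 1, max_iter = 100) {
  check_boxes(boxes)
  wh <- unique(cbind(boxes$w, boxes$h))
  stopifnot(k >= 1)
  if (nrow(wh) < k)
    stop("k = ", k, " exceeds the ", nrow(wh), " distinct box shapes")
  all_wh <- cbind(boxes$w, boxes$h)
  if (any(all_wh <= 0)) stop("anchor estimation needs positive box sizes")

  centres <- with_seed(seed, {
    # k-means++ seeding under the 1 - IoU distance
    ctr <- all_wh[sample.int(nrow(all_wh), 1), , drop = FALSE]
    while (nrow(ctr) < k) {
      d <- 1 - apply(shape_iou(all_wh, ctr), 1, max)
      if (sum(d) == 0) d <- rep(1, length(d))
      ctr <- rbind(ctr, all_wh[sample.int(nrow(all_wh), 1, prob = d), ])
    }
    ctr
  })

  objective <- function(ctr) mean(1 - apply(shape_iou(all_wh, ctr), 1, max))
  obj <- objective(centres)
  for (it in seq_len(max_iter)) {
    assign_to <- max.col(shape_iou(all_wh, centres), ties.method = "first")
    new_centres <- centres
    for (j in seq_len(k)) {
      m <- assign_to == j
      if (any(m)) new_centres[j, ] <- colMeans(all_wh[m, , drop = FALSE])
    }
    new_obj <- objective(new_centres)
    if (new_obj >= obj - 1e-12) break   # would not improve: keep previous
    centres <- new_centres
    obj <- new_obj
  }

  ord <- order(centres[, 1] * centres[, 2])
  centres <- centres[ord, , drop = FALSE]
  colnames(centres) <- c("w", "h")
  n_coarse <- ceiling(k / 2)
  fine_idx <- seq_len(k - n_coarse)
  structure(list(anchors = centres,
                 fine = centres[fine_idx, , drop = FALSE],
                 coarse = centres[setdiff(seq_len(k), fine_idx), ,
                                  drop = FALSE],
                 mean_iou = 1 - obj),
            class = "anchor_set")
}

# IoU between box shapes and anchor shapes at a common centre:
# rows = boxes, cols = anchors.
shape_iou <- function(wh, anchors) {
  inter <- outer(wh[, 1], anchors[, 1], pmin) * outer(wh[, 2], anchors[, 2], pmin)
  un <- outer(wh[, 1] * wh[, 2], anchors[, 1] * anchors[, 2], "+") - inter
  inter / un
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("anchor_set: %d anchors (%d fine + %d coarse), mean best IoU %.3f\n",
              nrow(x$anchors), nrow(x$fine), nrow(x$coarse), x$mean_iou))
  invisible(x)
}
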