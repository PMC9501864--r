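# Independent brute-force oracles for the evaluation metrics. These are
# deliberately naive re-derivations from the definitions and share no code
# with the package implementation.

oracle_iou <- function(a, b) {
  ax1 <- a$x; ax2 <- a$x + a$w; ay1 <- a$y; ay2 <- a$y + a$h
  bx1 <- b$x; bx2 <- b$x + b$w; by1 <- b$y; by2 <- b$y + b$h
  iw <- min(ax2, bx2) - max(ax1, bx1)
  ih <- min(ay2, by2) - max(ay1, by1)
  inter <- max(0, iw) * max(0, ih)
  inter / (a$w * a$h + b$w * b$h - inter)
}

# Greedy matching oracle: detections in descending confidence claim the
# free ground truth of highest IoU if >= iou_min.
oracle_match <- function(preds, truths, iou_min = 0.5) {
  free <- rep(TRUE, nrow(truths))
  tp <- 0
  gt_iou <- numeric(nrow(truths))
  if (nrow(preds) > 0) {
    for (i in order(preds$score, decreasing = TRUE)) {
      best_j <- 0; best <- -1
      for (j in seq_len(max(nrow(truths), 0))) {
        if (!free[j]) next
        v <- oracle_iou(preds[i, ], truths[j, ])
        if (v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0 && best >= iou_min) {
        free[best_j] <- FALSE
        tp <- tp + 1
        gt_iou[best_j] <- best
      }
    }
  }
  list(tp = tp, fp = nrow(preds) - tp, fn = sum(free), gt_iou = gt_iou)
}

# AP oracle: enumerate every confidence cut-point, recompute precision and
# recall from scratch at each, then integrate the precision envelope over
# recall.
oracle_ap <- function(preds, truths, iou_min = 0.5) {
  n_gt <- nrow(truths)
  if (nrow(preds) == 0) return(0)
  cuts <- sort(unique(preds$score), decreasing = TRUE)
  pts <- data.frame(recall = 0, precision = 0)
  for (t in cuts) {
    kept <- preds[preds$score >= t, , drop = FALSE]
    tp <- 0; fp <- 0
    for (id in unique(c(kept$image_id, truths$image_id))) {
      m <- oracle_match(kept[kept$image_id == id, , drop = FALSE],
                        truths[truths$image_id == id, , drop = FALSE],
                        iou_min)
      tp <- tp + m$tp; fp <- fp + m$fp
    }
    pts <- rbind(pts, data.frame(recall = tp / n_gt,
                                 precision = tp / max(1, tp + fp)))
  }
  pts <- pts[order(pts$recall), ]
  ap <- 0
  rs <- sort(unique(pts$recall))
  for (k in seq_along(rs)) {
    if (k == 1) { prev <- 0 } else prev <- rs[k - 1]
    if (rs[k] == 0) next
    p_env <- max(pts$precision[pts$recall >= rs[k]])
    ap <- ap + (rs[k] - prev) * p_env
  }
  ap
}

# Random single-class detection scenes for property tests.
random_scene <- function(n_img = 3, max_gt = 3, max_pred = 4, cls = "vein") {
  truths <- NULL; preds <- NULL
  for (id in seq_len(n_img)) {
    for (j in seq_len(sample(0:max_gt, 1))) {
      b <- bbox(runif(1, 0, 80), runif(1, 0, 80), runif(1, 5, 30),
                runif(1, 5, 30), cls)
      b$image_id <- id
      truths <- rbind(truths, b)
    }
    for (j in seq_len(sample(0:max_pred, 1))) {
      if (!is.null(truths) && runif(1) < 0.6 &&
          sum(truths$image_id == id) > 0) {
        # jittered copy of a ground truth in this image
        tt <- truths[truths$image_id == id, , drop = FALSE]
        t1 <- tt[sample(nrow(tt), 1), ]
        b <- bbox(t1$x + runif(1, -4, 4), t1$y + runif(1, -4, 4),
                  t1$w * runif(1, 0.8, 1.2), t1$h * runif(1, 0.8, 1.2),
                  cls, score = runif(1))
      } else {
        b <- bbox(runif(1, 0, 80), runif(1, 0, 80), runif(1, 5, 30),
                  runif(1, 5, 30), cls, score = runif(1))
      }
      b$image_id <- id
      preds <- rbind(preds, b)
    }
  }
  if (is.null(truths)) { truths <- empty_boxes(); truths$image_id <- integer(0) }
  if (is.null(preds)) { preds <- empty_boxes(); preds$image_id <- integer(0) }
  list(preds = preds, truths = truths)
}
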