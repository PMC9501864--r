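#' Match detections to ground truth within one image and class
#'
#' Greedy IoU-gated assignment in descending confidence order: each detection
#' claims the unmatched ground truth with which it has the highest IoU,
#' provided that IoU is at least `iou_min` (a true positive). Detections that
#' claim nothing -- including surplus detections overlapping an
#' already-claimed ground truth -- are false positives; unmatched ground
#' truths are false negatives. Exact IoU ties are broken toward the
#' lowest-index ground truth.
#'
#' The per-image IoU sample feeding the mean-IoU distribution is the mean over
#' ground truths of their matched IoU (0 for a ground truth left without a
#' matching detection). An image with detections but no ground truth
#' contributes a sample of 0; an image with neither contributes no sample.
#'
#' @param preds detection data frame (`x, y, w, h, class, score`), one class.
#' @param truths ground-truth data frame, same single class.
#' @param iou_min minimum IoU for a true positive (default 0.5).
#' @return A `match_result` list: counts `tp`, `fp`, `fn`; `gt_iou`, the
#'   per-ground-truth matched IoU (0 when unmatched); `iou_sample`, the image's
#'   contribution to the mIoU distribution (`NA` when the image has neither
#'   detections nor ground truth); `pred_is_tp`, logical per detection in
#'   descending-confidence order; `ord`, the ordering applied to `preds`.
#' @export
match_image <- function(preds, truths, iou_min = 0.5) {
  check_boxes(preds, need_score = nrow(preds) > 0)
  check_boxes(truths)
  cls <- unique(c(preds$class, truths$class))
  if (length(cls) > 1)
    stop("match_image expects a single class; got: ", paste(cls, collapse = ", "))
  np <- nrow(preds); nt <- nrow(truths)
  ord <- if (np > 0) order(-preds$score) else integer(0)
  preds <- preds[ord, , drop = FALSE]
  gt_iou <- numeric(nt)
  gt_taken <- logical(nt)
  pred_is_tp <- logical(np)
  if (np > 0 && nt > 0) {
    m <- iou_matrix(preds, truths)
    for (i in seq_len(np)) {
      cand <- which(!gt_taken & m[i, ] >= iou_min)
      if (length(cand) > 0) {
        j <- cand[which.max(m[i, cand])]   # which.max -> lowest index on ties
        gt_taken[j] <- TRUE
        gt_iou[j] <- m[i, j]
        pred_is_tp[i] <- TRUE
      }
    }
  }
  tp <- sum(pred_is_tp)
  iou_sample <- if (nt > 0) mean(gt_iou) else if (np > 0) 0 else NA_real_
  structure(list(tp = tp, fp = np - tp, fn = nt - tp,
                 gt_iou = gt_iou, iou_sample = iou_sample,
                 pred_is_tp = pred_is_tp, ord = ord),
            class = "match_result")
}

#' Precision-recall curve and average precision for one class
#'
#' Detections are pooled over images and processed in descending confidence
#' order; each is a true positive if it claims an unmatched ground truth in
#' its own image at IoU >= `iou_min`, using the same greedy rule as
#' [match_image()]. Average precision is the area under the resulting
#' precision-recall curve; the default uses the all-point interpolated
#' (precision-envelope) convention, `interpolation = "trapezoid"` integrates
#' the raw curve.
#'
#' @param preds detections with an `image_id` column, one class.
#' @param truths ground truths with an `image_id` column, same class.
#' @param iou_min minimum IoU for a true positive.
#' @param interpolation `"envelope"` (default) or `"trapezoid"`.
#' @return list with `curve` (data frame `score`, `precision`, `recall`) and
#'   `ap`.
#' @export
pr_curve_and_ap <- function(preds, truths, iou_min = 0.5,
                            interpolation = c("envelope", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  if (nrow(truths) == 0)
    stop("average precision is undefined with zero ground truths")
  stopifnot("image_id" %in% names(truths))
  if (nrow(preds) > 0) stopifnot("image_id" %in% names(preds))
  n_gt <- nrow(truths)
  if (nrow(preds) == 0) {
    return(list(curve = data.frame(score = numeric(0), precision = numeric(0),
                                   recall = numeric(0)), ap = 0))
  }
  ord <- order(-preds$score)
  preds <- preds[ord, , drop = FALSE]
  taken <- logical(n_gt)
  is_tp <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    sel <- which(truths$image_id == preds$image_id[i] & !taken)
    if (length(sel) > 0) {
      ious <- iou_matrix(preds[i, , drop = FALSE], truths[sel, , drop = FALSE])[1, ]
      ok <- which(ious >= iou_min)
      if (length(ok) > 0) {
        j <- sel[ok[which.max(ious[ok])]]
        taken[j] <- TRUE
        is_tp[i] <- TRUE
      }
    }
  }
  ctp <- cumsum(is_tp)
  cfp <- cumsum(!is_tp)
  precision <- ctp / (ctp + cfp)
  recall <- ctp / n_gt
  curve <- data.frame(score = preds$score, precision = precision, recall = recall)
  ap <- average_precision(precision, recall, interpolation)
  list(curve = curve, ap = ap)
}

# Area under a cumulative PR curve. `precision`/`recall` are the cumulative
# values at each detection, recall nondecreasing.
average_precision <- function(precision, recall,
                              interpolation = c("envelope", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  if (length(recall) == 0) return(0)
  if (interpolation == "envelope") {
    r <- c(0, recall)
    p <- c(0, precision)
    # precision envelope: max precision at any recall >= r
    p <- rev(cummax(rev(p)))
    sum(diff(r) * p[-1])
  } else {
    r <- c(0, recall)
    p <- c(precision[1], precision)
    sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
  }
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; `NA` when both are zero or either is `NA`.
#' @param precision,recall values in `[0, 1]`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Per-class summary of detection performance
#'
#' Aggregates per-image match results for one class into the summary-table
#' row: percent TP/FP/FN (as percentages of TP + FP + FN), mean IoU over the
#' per-image IoU distribution (zeros included, images with neither detections
#' nor ground truth excluded), precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1, and the supplied average precision. Undefined ratios (0/0) are
#' reported as `NA`, not 0.
#'
#' @param matches list of [match_image()] results for one class over a test set.
#' @param ap average precision for the class (from [pr_curve_and_ap()]).
#' @param class class label for the row.
#' @return One-row data frame with columns `class`, `pct_tp`, `pct_fp`,
#'   `pct_fn`, `miou`, `precision`, `recall`, `f1`, `ap`.
#' @export
summarize_class <- function(matches, ap = NA_real_, class = NA_character_) {
  stopifnot(length(matches) > 0)
  tp <- sum(vapply(matches, `[[`, numeric(1), "tp"))
  fp <- sum(vapply(matches, `[[`, numeric(1), "fp"))
  fn <- sum(vapply(matches, `[[`, numeric(1), "fn"))
  samples <- vapply(matches, `[[`, numeric(1), "iou_sample")
  samples <- samples[!is.na(samples)]
  total <- tp + fp + fn
  pct <- function(k) if (total == 0) NA_real_ else 100 * k / total
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  data.frame(class = class,
             pct_tp = pct(tp), pct_fp = pct(fp), pct_fn = pct(fn),
             miou = if (length(samples) == 0) NA_real_ else mean(samples),
             precision = precision, recall = recall,
             f1 = f1_score(precision, recall), ap = ap,
             stringsAsFactors = FALSE)
}

#' All-class average row for a detection summary table
#'
#' Unweighted arithmetic mean of every numeric column across the per-class
#' rows (`NA` cells excluded from their column's mean), appended as a row
#' labelled `"average"`. The mean of the `ap` column is the mAP and the mean
#' of `miou` the all-class average mIoU.
#'
#' @param summaries data frame of per-class rows from [summarize_class()].
#' @return `summaries` with the average row appended.
#' @export
summarize_all <- function(summaries) {
  stopifnot(nrow(summaries) >= 1)
  num <- vapply(summaries, is.numeric, logical(1))
  avg <- summaries[1, , drop = FALSE]
  avg$class <- "average"
  for (cn in names(summaries)[num])
    avg[[cn]] <- mean(summaries[[cn]], na.rm = TRUE)
  rbind(summaries, avg)
}

#' Evaluate detections against ground truth over a test set
#'
#' Runs the full per-class protocol: image-wise greedy matching at
#' `iou_min`, pooled precision-recall / average precision, and the summary
#' table with the all-class average row.
#'
#' @param preds detections with `image_id` column (all classes pooled).
#' @param truths ground truths with `image_id` column.
#' @param classes classes to evaluate (default: classes present in `truths`).
#' @param iou_min minimum IoU for a true positive.
#' @return list with `summary` (table incl. average row), `per_class`
#'   (match results and PR curves, named by class).
#' @export
evaluate_detections <- function(preds, truths, classes = NULL, iou_min = 0.5) {
  if (is.null(classes)) classes <- sort(unique(truths$class))
  image_ids <- sort(unique(c(preds$image_id, truths$image_id)))
  per_class <- list()
  rows <- list()
  for (cl in classes) {
    p_cl <- preds[preds$class == cl, , drop = FALSE]
    t_cl <- truths[truths$class == cl, , drop = FALSE]
    matches <- lapply(image_ids, function(id)
      match_image(p_cl[p_cl$image_id == id, , drop = FALSE],
                  t_cl[t_cl$image_id == id, , drop = FALSE], iou_min))
    pr <- if (nrow(t_cl) > 0) pr_curve_and_ap(p_cl, t_cl, iou_min)
          else list(curve = NULL, ap = NA_real_)
    per_class[[cl]] <- list(matches = matches, pr = pr)
    rows[[cl]] <- summarize_class(matches, ap = pr$ap, class = cl)
  }
  list(summary = summarize_all(do.call(rbind, rows)), per_class = per_class)
}
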