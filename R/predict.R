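#' Run inference on one image
#'
#' Decodes both head outputs against their anchors (sigmoid offsets within
#' the assigned grid cell, exponential width/height scaling of the anchor),
#' scores each predictor as sigmoid objectness times the best sigmoid class
#' score, drops detections below `conf_threshold`, clips boxes to the frame
#' and applies per-class non-maximum suppression at `nms_iou`.
#'
#' @param model a trained [build_model()] network.
#' @param image a `phantom_image` or an `(S, S, 3)` pixel array matching the
#'   model input size.
#' @param conf_threshold minimum confidence kept (default 0.5).
#' @param nms_iou IoU above which a lower-confidence same-class detection is
#'   suppressed (default 0.5).
#' @return Detection data frame (`x, y, w, h, class, score`), possibly empty.
#' @export
predict_image <- function(model, image, conf_threshold = 0.5, nms_iou = 0.5) {
  pixels <- if (is.list(image)) image$pixels else image
  S <- model$input_size
  stopifnot(all(dim(pixels) == c(S, S, 3)))
  x <- array(pixels, dim = c(S, S, 3, 1))
  raw <- model_forward_raw(model, x, training = FALSE)
  dets <- do.call(rbind, lapply(c("fine", "coarse"), function(h) {
    z <- raw[[h]]
    dim(z) <- dim(z)[1:3]
    anc <- model$anchors[[h]]
    g <- dim(z)[1]
    dec <- decode_head_grid(z, anc, model$strides[[h]], model$n_classes,
                            g, nrow(anc))
    score <- dec$obj * dec$cls_score
    keep <- score >= conf_threshold
    if (!any(keep)) return(NULL)
    data.frame(x = dec$x[keep], y = dec$y[keep], w = dec$w[keep],
               h = dec$h[keep],
               class = model$class_names[dec$cls[keep]],
               score = score[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(dets) || nrow(dets) == 0) return(empty_boxes())
  dets <- clip_boxes(dets, S)
  if (nrow(dets) == 0) return(empty_boxes())
  nms(dets, nms_iou)
}

#' Per-class non-maximum suppression
#'
#' Greedy: within each class, detections are visited in descending
#' confidence; a detection is suppressed when its IoU with an already kept
#' same-class detection exceeds `nms_iou`.
#'
#' @param dets detection data frame.
#' @param nms_iou suppression threshold.
#' @return The surviving detections, ordered by descending confidence.
#' @export
nms <- function(dets, nms_iou = 0.5) {
  check_boxes(dets, need_score = TRUE)
  out <- lapply(unique(dets$class), function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    keep <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      if (i == 1) { keep[1] <- TRUE; next }
      kept <- d[keep, , drop = FALSE]
      ious <- iou_matrix(d[i, , drop = FALSE], kept)[1, ]
      keep[i] <- all(ious <= nms_iou)
    }
    d[keep, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  out[order(-out$score), , drop = FALSE]
}

#' Predict over a list of images
#'
#' @param model trained network.
#' @param images list of images; names or indices become `image_id`s.
#' @param conf_threshold,nms_iou see [predict_image()].
#' @return Detections pooled into one data frame with an `image_id` column.
#' @export
predict_dataset <- function(model, images, conf_threshold = 0.5,
                            nms_iou = 0.5) {
  ids <- if (!is.null(names(images))) names(images) else seq_along(images)
  out <- lapply(seq_along(images), function(i) {
    d <- predict_image(model, images[[i]], conf_threshold, nms_iou)
    if (nrow(d) == 0) return(NULL)
    d$image_id <- ids[i]
    d
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- empty_boxes()
    out$image_id <- character(0)
  }
  out
}

# Ground-truth boxes of an image list pooled with image ids.
truth_table <- function(images) {
  ids <- if (!is.null(names(images))) names(images) else seq_along(images)
  out <- do.call(rbind, lapply(seq_along(images), function(i) {
    b <- images[[i]]$boxes
    if (is.null(b) || nrow(b) == 0) return(NULL)
    b$image_id <- ids[i]
    b
  }))
  if (is.null(out)) {
    out <- empty_boxes()
    out$image_id <- character(0)
  }
  out
}
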