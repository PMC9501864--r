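#' Bounding boxes
#'
#' Boxes are plain data frames with numeric columns `x`, `y`, `w`, `h`, a
#' character `class` column and, for detections, a numeric `score` column.
#' Coordinates are 0-based pixels with the origin at the top-left corner of the
#' image; a box covers the half-open extent `[x, x + w) x [y, y + h)`.
#' `x` is the left edge, `y` the top edge.
#'
#' @param x,y top-left corner, pixels (0-based).
#' @param w,h width and height, pixels (non-negative).
#' @param class feature class label, one of `"shrapnel"`, `"vein"`,
#'   `"artery"`, `"nerve"` (other labels are allowed for generic use).
#' @param score detection confidence in `[0, 1]`; `NA` for ground truth.
#' @return A one-row data frame.
#' @examples
#' bbox(10, 20, 30, 40, "artery")
#' @export
bbox <- function(x, y, w, h, class = "shrapnel", score = NA_real_) {
  stopifnot(is.finite(x), is.finite(y), w >= 0, h >= 0)
  data.frame(x = as.numeric(x), y = as.numeric(y),
             w = as.numeric(w), h = as.numeric(h),
             class = as.character(class), score = as.numeric(score),
             stringsAsFactors = FALSE)
}

#' @rdname bbox
#' @param ... one-row box data frames (or multi-row ones), row-bound.
#' @export
bbox_bind <- function(...) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (length(dfs) == 0) return(empty_boxes())
  do.call(rbind, dfs)
}

#' @rdname bbox
#' @export
empty_boxes <- function() {
  data.frame(x = numeric(0), y = numeric(0), w = numeric(0), h = numeric(0),
             class = character(0), score = numeric(0), stringsAsFactors = FALSE)
}

# Internal validator used at module boundaries.
check_boxes <- function(boxes, need_score = FALSE) {
  stopifnot(is.data.frame(boxes))
  need <- c("x", "y", "w", "h", "class")
  if (need_score) need <- c(need, "score")
  missing <- setdiff(need, names(boxes))
  if (length(missing) > 0)
    stop("box data frame lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(boxes) > 0) {
    stopifnot(all(is.finite(boxes$x)), all(is.finite(boxes$y)),
              all(boxes$w >= 0), all(boxes$h >= 0))
    if (need_score)
      stopifnot(all(boxes$score >= 0 & boxes$score <= 1))
  }
  invisible(boxes)
}

#' Intersection over union of two boxes
#'
#' Ratio of overlap area to union area for two axis-aligned boxes in the
#' `(x, y, w, h)` convention. Used to gate detection correctness at a minimum
#' IoU of 0.5 throughout the evaluation protocol.
#'
#' @param a,b one-row box data frames (class labels are ignored here).
#' @return A value in `[0, 1]`. Two zero-area boxes are an error, not 0.
#' @examples
#' iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)) # 1/3
#' @export
iou <- function(a, b) {
  check_boxes(a); check_boxes(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  area_a <- a$w * a$h
  area_b <- b$w * b$h
  if (area_a == 0 && area_b == 0)
    stop("IoU is undefined for two zero-area boxes")
  ix <- max(0, min(a$x + a$w, b$x + b$w) - max(a$x, b$x))
  iy <- max(0, min(a$y + a$h, b$y + b$h) - max(a$y, b$y))
  inter <- ix * iy
  inter / (area_a + area_b - inter)
}

# Pairwise IoU matrix: rows = boxes in `a`, cols = boxes in `b`.
# Zero-area boxes get IoU 0 against everything (vectorised contexts only).
iou_matrix <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) return(matrix(0, na, nb))
  ax2 <- a$x + a$w; ay2 <- a$y + a$h
  bx2 <- b$x + b$w; by2 <- b$y + b$h
  ix <- pmax(0, outer(ax2, bx2, pmin) - outer(a$x, b$x, pmax))
  iy <- pmax(0, outer(ay2, by2, pmin) - outer(a$y, b$y, pmax))
  inter <- ix * iy
  un <- outer(a$w * a$h, b$w * b$h, "+") - inter
  out <- inter / un
  out[un == 0] <- 0
  out
}

# Clip boxes to the frame [0, size) x [0, size); drops boxes whose clipped
# area is zero. `size` may be a scalar or c(width, height).
clip_boxes <- function(boxes, size) {
  if (nrow(boxes) == 0) return(boxes)
  sw <- size[1]; sh <- size[length(size)]
  x1 <- pmax(boxes$x, 0); y1 <- pmax(boxes$y, 0)
  x2 <- pmin(boxes$x + boxes$w, sw); y2 <- pmin(boxes$y + boxes$h, sh)
  boxes$x <- x1; boxes$y <- y1
  boxes$w <- pmax(0, x2 - x1); boxes$h <- pmax(0, y2 - y1)
  boxes[boxes$w > 0 & boxes$h > 0, , drop = FALSE]
}
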