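#' Box midpoint
#'
#' Centre of a box in the `(x, y, w, h)` convention: half the width added to
#' the left edge and half the height added to the top edge. Fractional
#' midpoints are preserved; nothing is rounded.
#'
#' @param box one-row box data frame.
#' @return Named numeric vector `c(mx, my)` in pixels.
#' @export
midpoint <- function(box) {
  check_boxes(box)
  stopifnot(nrow(box) == 1)
  c(mx = box$x + box$w / 2, my = box$y + box$h / 2)
}

#' Euclidean distance between two midpoints
#'
#' `sqrt((x2 - x1)^2 + (y2 - y1)^2)` in pixel units.
#'
#' @param p,q midpoints as returned by [midpoint()] (any length-2 numeric).
#' @export
pair_distance <- function(p, q) {
  sqrt((q[[1]] - p[[1]])^2 + (q[[2]] - p[[2]])^2)
}

# Fixed tie-break order when two features are equally close to the shrapnel:
# most critical first.
.closest_tie_order <- c("artery", "nerve", "vein")

#' Per-image triage record from detections
#'
#' Implements the triage filtering and measurement: an image is scored only
#' when detections for all four classes (shrapnel, vein, artery, nerve) are
#' present; for each class only the single highest-confidence detection is
#' used (confidence ties broken toward the larger box, then first seen).
#' The record holds the midpoint distances from shrapnel to vein, artery and
#' nerve, their minimum, and the closest feature (distance ties broken in the
#' fixed order artery, nerve, vein).
#'
#' @param dets detection data frame (`x, y, w, h, class, score`), all classes.
#' @param image_id identifier stored in the record.
#' @return A one-row data frame (`image_id`, `d_vein`, `d_artery`, `d_nerve`,
#'   `d_min`, `closest`), or `NULL` when the image is filtered out.
#' @export
triage_image <- function(dets, image_id = NA) {
  check_boxes(dets, need_score = nrow(dets) > 0)
  need <- c("shrapnel", "vein", "artery", "nerve")
  if (!all(need %in% dets$class)) return(NULL)
  pick <- function(cl) {
    d <- dets[dets$class == cl, , drop = FALSE]
    d <- d[order(-d$score, -(d$w * d$h)), , drop = FALSE]
    d[1, , drop = FALSE]
  }
  mids <- lapply(need, function(cl) midpoint(pick(cl)))
  names(mids) <- need
  d <- vapply(c("vein", "artery", "nerve"), function(cl)
    pair_distance(mids$shrapnel, mids[[cl]]), numeric(1))
  d_min <- min(d)
  closest <- .closest_tie_order[.closest_tie_order %in%
                                  names(d)[d == d_min]][1]
  data.frame(image_id = image_id, d_vein = d[["vein"]],
             d_artery = d[["artery"]], d_nerve = d[["nerve"]],
             d_min = d_min, closest = closest, stringsAsFactors = FALSE)
}

#' Reference artery diameter from ground-truth boxes
#'
#' Average ground-truth window size for the artery, operationalised as the
#' mean over artery boxes of `(w + h) / 2`. This is the reference length the
#' triage gate multiplies.
#'
#' @param truths ground-truth box data frame (any classes; artery rows used).
#' @return Reference diameter in pixels.
#' @export
reference_diameter <- function(truths) {
  check_boxes(truths)
  art <- truths[truths$class == "artery", , drop = FALSE]
  if (nrow(art) == 0) stop("no artery ground-truth boxes to average")
  mean((art$w + art$h) / 2)
}

#' Gate triage records against multiples of a reference diameter
#'
#' An image is flagged at multiplier `m` when its minimum shrapnel-to-feature
#' distance is strictly smaller than `m * reference_diameter`. The summary
#' reports the flagged fraction per multiplier together with per-feature
#' distance statistics and closest-feature frequencies.
#'
#' @param records data frame of [triage_image()] rows.
#' @param ref reference diameter in pixels (see [reference_diameter()]).
#' @param multipliers gating-window multipliers.
#' @return A `triage_summary` list: `n_images`, `mean_d_min`,
#'   `reference_diameter`, `feature_stats` (mean/max/min distance and
#'   closest-frequency percent per feature), `flagged` (data frame
#'   `multiplier`, `fraction` with fractions in percent).
#' @export
gate <- function(records, ref, multipliers = c(0.5, 0.75, 1.0, 1.25, 1.5)) {
  stopifnot(ref > 0, all(multipliers > 0))
  multipliers <- sort(multipliers)
  n <- if (is.null(records)) 0L else nrow(records)
  if (n == 0) {
    return(structure(list(n_images = 0L, mean_d_min = NA_real_,
                          reference_diameter = ref,
                          feature_stats = NULL,
                          flagged = data.frame(multiplier = multipliers,
                                               fraction = NA_real_)),
                     class = "triage_summary"))
  }
  feats <- c("vein", "artery", "nerve")
  feature_stats <- do.call(rbind, lapply(feats, function(cl) {
    d <- records[[paste0("d_", cl)]]
    data.frame(feature = cl, mean = mean(d), max = max(d), min = min(d),
               pct_closest = 100 * mean(records$closest == cl),
               stringsAsFactors = FALSE)
  }))
  flagged <- data.frame(
    multiplier = multipliers,
    fraction = vapply(multipliers, function(m)
      100 * mean(records$d_min < m * ref), numeric(1)))
  structure(list(n_images = n, mean_d_min = mean(records$d_min),
                 reference_diameter = ref, feature_stats = feature_stats,
                 flagged = flagged),
            class = "triage_summary")
}

#' @export
print.triage_summary <- function(x, ...) {
  cat(sprintf("Triage summary over %d images (reference diameter %.1f px)\n",
              x$n_images, x$reference_diameter))
  if (x$n_images > 0) {
    cat(sprintf("  mean minimum distance: %.1f px\n", x$mean_d_min))
    st <- x$feature_stats
    for (i in seq_len(nrow(st)))
      cat(sprintf("  %-6s mean %.1f  max %.1f  min %.1f  closest %.0f%%\n",
                  st$feature[i], st$mean[i], st$max[i], st$min[i],
                  st$pct_closest[i]))
    f <- x$flagged
    cat("  flagged:",
        paste(sprintf("%.2fx=%.0f%%", f$multiplier, f$fraction),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Triage a set of images end to end
#'
#' Applies [triage_image()] to each image's detections and gates the
#' surviving records with [gate()].
#'
#' @param preds detections with an `image_id` column.
#' @param truths ground truths used for the artery reference diameter.
#' @param multipliers gating-window multipliers.
#' @return list with `records` (per-image data frame) and `summary`
#'   (a `triage_summary`).
#' @export
triage_images <- function(preds, truths,
                          multipliers = c(0.5, 0.75, 1.0, 1.25, 1.5)) {
  ids <- unique(preds$image_id)
  recs <- do.call(rbind, lapply(ids, function(id)
    triage_image(preds[preds$image_id == id, , drop = FALSE], image_id = id)))
  ref <- reference_diameter(truths)
  list(records = recs, summary = gate(recs, ref, multipliers))
}
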