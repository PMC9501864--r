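coco_classes <- c("shrapnel", "vein", "artery", "nerve")

#' Write and read COCO-format annotations
#'
#' Ground truth is stored as COCO JSON: an `images` array (id, file name,
#' size), an `annotations` array with `bbox = [x, y, w, h]` in 0-based
#' top-left-origin pixels, and a `categories` array with ids 1-4 for
#' shrapnel, vein, artery, nerve. Detections use the COCO results layout
#' (`image_id`, `category_id`, `bbox`, `score`). Round-tripping annotations
#' through write and read is lossless.
#'
#' @param images list of `phantom_image` objects (or any list with `pixels`
#'   and `boxes`); names, if set, become image ids.
#' @param path output JSON file.
#' @return `write_coco_annotations()`: `path`, invisibly.
#'   `read_coco_annotations()`: list with `truths` (box data frame with
#'   `image_id`) and `images` (data frame `id`, `file_name`, `width`,
#'   `height`).
#' @export
write_coco_annotations <- function(images, path) {
  ids <- if (!is.null(names(images))) names(images) else
    as.character(seq_along(images))
  img_df <- data.frame(
    id = ids,
    file_name = paste0(ids, ".png"),
    width = vapply(images, function(im) dim(im$pixels)[2], numeric(1)),
    height = vapply(images, function(im) dim(im$pixels)[1], numeric(1)),
    stringsAsFactors = FALSE)
  ann <- list(); aid <- 0
  for (i in seq_along(images)) {
    b <- images[[i]]$boxes
    if (is.null(b) || nrow(b) == 0) next
    for (j in seq_len(nrow(b))) {
      aid <- aid + 1
      ann[[aid]] <- list(id = aid, image_id = ids[i],
                         category_id = match(b$class[j], coco_classes),
                         bbox = c(b$x[j], b$y[j], b$w[j], b$h[j]),
                         area = b$w[j] * b$h[j], iscrowd = 0)
    }
  }
  obj <- list(images = img_df, annotations = ann,
              categories = data.frame(id = seq_along(coco_classes),
                                      name = coco_classes,
                                      stringsAsFactors = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_annotations
#' @export
read_coco_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cats <- vapply(obj$categories, function(c) c$name, character(1))
  cat_ids <- vapply(obj$categories, function(c) c$id, numeric(1))
  truths <- do.call(rbind, lapply(obj$annotations, function(a) {
    b <- unlist(a$bbox)
    df <- bbox(b[1], b[2], b[3], b[4],
               class = cats[match(a$category_id, cat_ids)])
    df$image_id <- as.character(a$image_id)
    df
  }))
  if (is.null(truths)) {
    truths <- empty_boxes(); truths$image_id <- character(0)
  }
  images <- do.call(rbind, lapply(obj$images, function(im)
    data.frame(id = as.character(im$id), file_name = im$file_name,
               width = im$width, height = im$height,
               stringsAsFactors = FALSE)))
  list(truths = truths, images = images)
}

#' @rdname write_coco_annotations
#' @param dets detection data frame with `image_id` column.
#' @export
write_coco_detections <- function(dets, path) {
  recs <- lapply(seq_len(nrow(dets)), function(i)
    list(image_id = dets$image_id[i],
         category_id = match(dets$class[i], coco_classes),
         bbox = c(dets$x[i], dets$y[i], dets$w[i], dets$h[i]),
         score = dets$score[i]))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_coco_annotations
#' @export
read_coco_detections <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- do.call(rbind, lapply(recs, function(r) {
    b <- unlist(r$bbox)
    df <- bbox(b[1], b[2], b[3], b[4], class = coco_classes[r$category_id],
               score = r$score)
    df$image_id <- as.character(r$image_id)
    df
  }))
  if (is.null(out)) {
    out <- empty_boxes(); out$image_id <- character(0)
  }
  out
}

#' Flat CSV mirror of box annotations
#' @param boxes box data frame with `image_id`.
#' @param path CSV file.
#' @export
write_boxes_csv <- function(boxes, path) {
  utils::write.csv(boxes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_boxes_csv
#' @export
read_boxes_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write an image raster as 8-bit PNG
#' @param image `phantom_image` or `(H, W, 3)` array in `[0, 1]`.
#' @param path PNG file.
#' @export
write_image_png <- function(image, path) {
  pixels <- if (is.list(image)) image$pixels else image
  png::writePNG(pixels, path)
  invisible(path)
}

#' Crop and resize an image with its boxes
#'
#' Crops the raster to `crop = c(x, y, w, h)` (0-based pixels; `NULL` means
#' no crop) -- e.g. to remove instrument settings from view -- then resizes
#' to `size` x `size` x 3 by nearest-neighbour sampling. Box coordinates are
#' mapped through the same affine transform. Single-channel input is
#' replicated to three identical planes.
#'
#' @param pixels `(H, W)` matrix or `(H, W, C)` array in `[0, 1]`.
#' @param boxes box data frame in the input coordinate frame.
#' @param crop crop window `c(x, y, w, h)` or `NULL`.
#' @param size output side length.
#' @return list with `pixels` (`size` x `size` x 3) and `boxes`.
#' @export
preprocess <- function(pixels, boxes = empty_boxes(), crop = NULL,
                       size = 512) {
  if (length(dim(pixels)) == 2)
    pixels <- array(pixels, dim = c(dim(pixels), 1))
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  if (H == 0 || W == 0) stop("empty raster")
  if (is.null(crop)) crop <- c(0, 0, W, H)
  if (crop[1] < 0 || crop[2] < 0 || crop[1] + crop[3] > W ||
      crop[2] + crop[4] > H || crop[3] <= 0 || crop[4] <= 0)
    stop("crop window lies outside the raster")
  cols <- (crop[1] + 1):(crop[1] + crop[3])
  rows <- (crop[2] + 1):(crop[2] + crop[4])
  cropped <- pixels[rows, cols, , drop = FALSE]
  sx <- size / crop[3]; sy <- size / crop[4]
  src_c <- pmin(pmax(ceiling((seq_len(size) - 0.5) / sx), 1), crop[3])
  src_r <- pmin(pmax(ceiling((seq_len(size) - 0.5) / sy), 1), crop[4])
  resized <- cropped[src_r, src_c, , drop = FALSE]
  if (dim(resized)[3] == 1)
    resized <- array(resized[, , 1], dim = c(size, size, 3))
  if (nrow(boxes) > 0) {
    boxes$x <- (boxes$x - crop[1]) * sx
    boxes$y <- (boxes$y - crop[2]) * sy
    boxes$w <- boxes$w * sx
    boxes$h <- boxes$h * sy
    boxes <- clip_boxes(boxes, size)
  }
  list(pixels = resized, boxes = boxes)
}

# ---- model serialization ---------------------------------------------------

#' Save and load model checkpoints
#'
#' Parameters (and batch-norm running statistics) are extracted into plain
#' lists and stored with the architecture description, so a checkpoint can be
#' restored with `load_model()` alone.
#'
#' @param model a `shrapod_model`.
#' @param path checkpoint file (RDS).
#' @export
save_model <- function(model, path) {
  params <- lapply(model$nodes, function(n)
    if (is.null(n$par)) NULL else as.list(n$par))
  names(params) <- vapply(model$nodes, `[[`, character(1), "name")
  obj <- list(anchors = model$anchors, input_size = model$input_size,
              n_classes = model$n_classes, class_names = model$class_names,
              width = model$width, params = params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$anchors, input_size = obj$input_size,
                       n_classes = obj$n_classes, width = obj$width,
                       class_names = obj$class_names)
  for (i in seq_along(model$nodes)) {
    nm <- model$nodes[[i]]$name
    if (!is.null(obj$params[[nm]]))
      model$nodes[[i]]$par <- list2env(obj$params[[nm]],
                                       parent = emptyenv())
  }
  model
}
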