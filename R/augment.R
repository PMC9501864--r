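#' Training-time augmentation of an annotated image
#'
#' Applies an independent random horizontal flip, vertical flip, uniform
#' scaling in `[0.8, 1.2]` and rotation in `[-360, 360]` degrees about the
#' image centre, to the raster and its boxes together. Each box is
#' transformed by mapping its four corners through the same affine map and
#' taking the enclosing axis-aligned rectangle, then clipping to the frame;
#' the raster is resampled by nearest-neighbour inverse mapping. The
#' transform order is flip, then scale, then rotate.
#'
#' If any box leaves the frame entirely, the draw is rejected and new random
#' parameters are sampled (bounded retries; the unaugmented image is returned
#' if every retry fails). With forced (non-`NULL`) parameters no resampling
#' happens and fully exited boxes are dropped. Degenerate zero-area boxes are
#' always removed.
#'
#' Randomness is drawn from the caller's RNG stream; seed it for
#' reproducibility.
#'
#' @param image a `phantom_image` (or any list with `pixels`, `boxes`, `meta`).
#' @param hflip,vflip force a flip (`TRUE`/`FALSE`) or sample it (`NULL`).
#' @param scale force a scale factor or sample from `[0.8, 1.2]` (`NULL`).
#' @param angle force a rotation angle in degrees or sample (`NULL`).
#' @param fill background fill intensity for pixels mapped from outside.
#' @param max_retries resampling attempts when a box fully exits the frame.
#' @return The augmented `phantom_image`. Feature masks kept in `meta$masks`
#'   are transformed alongside the raster.
#' @export
augment_sample <- function(image, hflip = NULL, vflip = NULL, scale = NULL,
                           angle = NULL, fill = 0.02, max_retries = 10) {
  check_boxes(image$boxes)
  forced <- !(is.null(hflip) && is.null(vflip) && is.null(scale) &&
                is.null(angle))
  draw <- function() {
    list(hflip = if (is.null(hflip)) stats::runif(1) < 0.5 else hflip,
         vflip = if (is.null(vflip)) stats::runif(1) < 0.5 else vflip,
         scale = if (is.null(scale)) stats::runif(1, 0.8, 1.2) else scale,
         angle = if (is.null(angle)) stats::runif(1, -360, 360) else angle)
  }
  n_try <- if (forced) 1L else max_retries
  for (try in seq_len(n_try)) {
    par <- draw()
    out <- apply_affine(image, par, fill)
    if (forced || !out$any_box_lost) {
      image$pixels <- out$pixels
      image$boxes <- out$boxes
      if (!is.null(image$meta$masks)) image$meta$masks <- out$masks
      return(image)
    }
  }
  image  # every retry lost a box: fall back to the unaugmented sample
}

# Forward affine about the image centre: q = R(angle) %*% diag(scale) %*%
# F(flips) %*% (p - c) + c, in 0-based continuous pixel coordinates.
affine_matrix <- function(par) {
  th <- par$angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Fm <- diag(c(if (par$hflip) -1 else 1, if (par$vflip) -1 else 1))
  R %*% (par$scale * Fm)
}

apply_affine <- function(image, par, fill) {
  S <- dim(image$pixels)[1]
  ctr <- S / 2
  M <- affine_matrix(par)
  Minv <- solve(M)

  # raster: inverse-map each target pixel centre, nearest neighbour
  xs <- seq_len(S) - 0.5
  Xq <- matrix(xs, S, S, byrow = TRUE) - ctr
  Yq <- matrix(xs, S, S) - ctr
  xs_src <- Minv[1, 1] * Xq + Minv[1, 2] * Yq + ctr
  ys_src <- Minv[2, 1] * Xq + Minv[2, 2] * Yq + ctr
  col_src <- round(xs_src + 0.5)
  row_src <- round(ys_src + 0.5)
  ok <- as.vector(col_src >= 1 & col_src <= S & row_src >= 1 & row_src <= S)
  idx <- cbind(as.vector(pmin(pmax(row_src, 1), S)),
               as.vector(pmin(pmax(col_src, 1), S)))
  warp <- function(m, bg) {
    out <- matrix(bg, S, S)
    out[ok] <- m[idx[ok, , drop = FALSE]]
    out
  }
  plane <- warp(image$pixels[, , 1], fill)
  pixels <- array(plane, dim = c(S, S, 3))

  # boxes: forward-map the four corners, enclose, clip
  boxes <- image$boxes
  any_box_lost <- FALSE
  if (nrow(boxes) > 0) {
    new_rows <- lapply(seq_len(nrow(boxes)), function(i) {
      b <- boxes[i, ]
      cx <- c(b$x, b$x + b$w, b$x, b$x + b$w) - ctr
      cy <- c(b$y, b$y, b$y + b$h, b$y + b$h) - ctr
      qx <- M[1, 1] * cx + M[1, 2] * cy + ctr
      qy <- M[2, 1] * cx + M[2, 2] * cy + ctr
      enc <- bbox(min(qx), min(qy), max(qx) - min(qx), max(qy) - min(qy),
                  class = b$class, score = b$score)
      clip_boxes(enc, S)
    })
    kept <- vapply(new_rows, nrow, integer(1)) > 0
    any_box_lost <- any(!kept)
    boxes <- if (any(kept)) do.call(rbind, new_rows[kept]) else empty_boxes()
    if (any_box_lost && !is.null(image$meta$masks))
      image$meta$masks <- image$meta$masks[kept]
  }
  masks <- NULL
  if (!is.null(image$meta$masks))
    masks <- lapply(image$meta$masks, warp, bg = FALSE)
  list(pixels = pixels, boxes = boxes, masks = masks,
       any_box_lost = any_box_lost)
}

#' Split a dataset into train / validation / test parts
#'
#' Random, seed-deterministic partition with largest-remainder rounding of
#' the requested fractions; every part is kept non-empty by borrowing from
#' the largest part if rounding empties one. The split tag is recorded in
#' each image's `meta$split`. Validation and test images are never augmented
#' downstream.
#'
#' @param images list of `phantom_image` objects (length >= 3).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed seed for the permutation.
#' @return Named list of disjoint image lists: `train`, `val`, `test`; their
#'   union is the input.
#' @export
split_dataset <- function(images, fractions = c(0.75, 0.10, 0.15), seed = 1) {
  n <- length(images)
  if (n < 3) stop("need at least 3 images to form a three-way split")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  stopifnot(length(fractions) == 3)
  counts <- largest_remainder(n, fractions)
  # keep every part non-empty
  while (any(counts == 0)) {
    counts[which.max(counts)] <- max(counts) - 1L
    counts[which(counts == 0)[1]] <- 1L
  }
  perm <- with_seed(seed, sample.int(n))
  parts <- split(perm, rep(c("train", "val", "test"), counts))
  out <- lapply(c(train = "train", val = "val", test = "test"), function(tag) {
    lapply(images[sort(parts[[tag]])], function(im) {
      im$meta$split <- tag
      im
    })
  })
  out
}

largest_remainder <- function(n, fractions) {
  exact <- n * fractions
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
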