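#' Configuration for the synthetic ultrasound phantom generator
#'
#' Describes the emulated gelatin thigh phantom: a speckled two-layer
#' (fat over muscle) background with a deep bone arc, an anechoic circular
#' artery with a bright wall, a darker compressed-oval vein, a hypoechoic
#' stippled nerve lateral to the artery, and -- in a configurable fraction of
#' images -- a bright metallic shrapnel rod. All physical dimensions are in
#' millimetres and are converted through `px_per_mm`.
#'
#' The default pixel scale (9.4 px/mm at 512 px) makes the artery
#' ground-truth box average about 75 px, the reference size the triage gate
#' is expressed against. When generating at a smaller `image_size`, scale
#' `px_per_mm` proportionally to keep the same field of view.
#'
#' @param image_size raster side length in pixels (square images).
#' @param px_per_mm pixel pitch, px per mm.
#' @param shrapnel_prob probability that an image contains a shrapnel rod.
#' @param shrapnel_len_mm length range (min, max) of the rod, mm.
#' @param shrapnel_diam_mm rod diameter, mm.
#' @param artery_diam_mm artery lumen diameter, mm.
#' @param vein_minor_mm vein minor (vertical) axis, mm.
#' @param nerve_diam_mm nerve bundle diameter, mm.
#' @param bone_diam_mm bone diameter, mm (only the top arc is in view).
#' @param layer_boundary_frac fraction of image height at which the
#'   fat/muscle interface sits.
#' @param intensities named list of mean echogenicities in `[0, 1]` for
#'   `fat`, `muscle`, `interface`, `bone`, `artery`, `artery_rim`, `vein`,
#'   `nerve`, `shrapnel`.
#' @param speckle_scale multiplicative speckle strength (0 disables).
#' @param log_compression amplitude-compression strength (0 disables).
#' @param shrapnel_shadow draw a distal acoustic shadow under the rod.
#' @param max_place_retries placement retries before a config is rejected.
#' @return A validated `phantom_config` list.
#' @export
phantom_config <- function(image_size = 512,
                           px_per_mm = 9.4 * image_size / 512,
                           shrapnel_prob = 0.6,
                           shrapnel_len_mm = c(2, 10),
                           shrapnel_diam_mm = 2.5,
                           artery_diam_mm = 8,
                           vein_minor_mm = 6.5,
                           nerve_diam_mm = 6.5,
                           bone_diam_mm = 26,
                           layer_boundary_frac = 0.3,
                           intensities = list(
                             fat = 0.50, muscle = 0.30, interface = 0.78,
                             bone = 0.88, artery = 0.04, artery_rim = 0.80,
                             vein = 0.08, nerve = 0.46, shrapnel = 0.97),
                           speckle_scale = 0.35,
                           log_compression = 3,
                           shrapnel_shadow = FALSE,
                           max_place_retries = 40) {
  cfg <- list(image_size = as.integer(image_size), px_per_mm = px_per_mm,
              shrapnel_prob = shrapnel_prob,
              shrapnel_len_mm = as.numeric(shrapnel_len_mm),
              shrapnel_diam_mm = shrapnel_diam_mm,
              artery_diam_mm = artery_diam_mm, vein_minor_mm = vein_minor_mm,
              nerve_diam_mm = nerve_diam_mm, bone_diam_mm = bone_diam_mm,
              layer_boundary_frac = layer_boundary_frac,
              intensities = intensities, speckle_scale = speckle_scale,
              log_compression = log_compression,
              shrapnel_shadow = shrapnel_shadow,
              max_place_retries = as.integer(max_place_retries))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
}

validate_phantom_config <- function(cfg) {
  dims <- c(cfg$px_per_mm, cfg$shrapnel_len_mm, cfg$shrapnel_diam_mm,
            cfg$artery_diam_mm, cfg$vein_minor_mm, cfg$nerve_diam_mm,
            cfg$bone_diam_mm)
  if (!all(dims > 0)) stop("all physical dimensions must be strictly positive")
  if (cfg$shrapnel_prob < 0 || cfg$shrapnel_prob > 1)
    stop("shrapnel_prob must lie in [0, 1]")
  if (cfg$shrapnel_len_mm[1] > cfg$shrapnel_len_mm[2])
    stop("shrapnel_len_mm must be an increasing (min, max) pair")
  if (cfg$px_per_mm * cfg$artery_diam_mm >= cfg$image_size)
    stop("artery does not fit in the frame at this pixel scale")
  if (cfg$layer_boundary_frac <= 0 || cfg$layer_boundary_frac >= 1)
    stop("layer_boundary_frac must lie in (0, 1)")
  cfg
}

# Run `expr` under a private Mersenne-Twister stream seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

# 3x3 box blur with edge replication; gives the speckle field a short
# spatial correlation length.
blur3 <- function(m) {
  n <- nrow(m)
  p <- m[c(1, 1:n, n), c(1, 1:n, n)]
  acc <- matrix(0, n, n)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + p[di + 1:n, dj + 1:n]
  acc / 9
}

# Tight axis-aligned box around TRUE pixels of a logical matrix, in the
# 0-based (x, y, w, h) convention. NULL when the mask is empty.
mask_to_box <- function(mask, class, score = NA_real_) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  r <- range(idx[, 1]); cc <- range(idx[, 2])
  bbox(cc[1] - 1, r[1] - 1, cc[2] - cc[1] + 1, r[2] - r[1] + 1,
       class = class, score = score)
}

#' Generate one annotated synthetic phantom image
#'
#' Renders the layered speckle background and features described by a
#' [phantom_config()] and derives ground-truth boxes as the tightest
#' axis-aligned rectangles around each rendered feature mask. Output is
#' bit-reproducible for a fixed `(config, seed)` pair. The shrapnel rod is
#' re-placed (up to `max_place_retries` times) until it does not touch the
#' vein, artery or nerve; a configuration in which this cannot be achieved is
#' rejected with an error.
#'
#' @param config a [phantom_config()].
#' @param seed integer seed for this image's private random stream.
#' @param keep_masks keep the per-feature logical masks (row order matching
#'   `boxes`) in `meta$masks`; used for geometry checks.
#' @return A `phantom_image`: list with `pixels` (`image_size` x
#'   `image_size` x 3 array in `[0, 1]`, identical channel planes), `boxes`
#'   (ground-truth data frame) and `meta` (`seed`, `shrapnel_present`,
#'   `split`).
#' @examples
#' img <- generate_phantom(phantom_config(image_size = 128), seed = 7)
#' img$boxes
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1,
                             keep_masks = FALSE) {
  validate_phantom_config(config)
  with_seed(seed, {
    S <- config$image_size
    mm <- config$px_per_mm
    iv <- config$intensities
    xs <- seq_len(S) - 0.5              # 0-based pixel-centre coordinates
    X <- matrix(xs, S, S, byrow = TRUE) # X[i, j] = x of column j
    Y <- matrix(xs, S, S)               # Y[i, j] = y of row i

    # --- layered background -------------------------------------------------
    boundary <- (config$layer_boundary_frac + stats::runif(1, -0.03, 0.03)) * S
    base <- matrix(iv$muscle, S, S)
    base[Y < boundary] <- iv$fat
    base[abs(Y - boundary) <= 1.5] <- iv$interface
    # heterogeneous muscle texture: a few soft bright/dark patches
    n_patch <- 6
    px <- stats::runif(n_patch, 0, S); py <- stats::runif(n_patch, boundary, S)
    pr <- stats::runif(n_patch, 0.02, 0.06) * S
    pa <- stats::runif(n_patch, -0.08, 0.08)
    for (k in seq_len(n_patch)) {
      d2 <- (X - px[k])^2 + (Y - py[k])^2
      base <- base + pa[k] * exp(-d2 / (2 * pr[k]^2))
    }

    # --- bone: bright top arc near the bottom, shadow beneath ---------------
    r_b <- config$bone_diam_mm * mm / 2
    bx <- S / 2 + stats::runif(1, -0.08, 0.08) * S
    by <- S + 0.35 * r_b                 # centre below the frame: arc in view
    D_b <- sqrt((X - bx)^2 + (Y - by)^2)
    base[abs(D_b - r_b) <= 2.5 & Y <= by] <- iv$bone
    shadow <- (D_b < r_b - 2.5)
    base[shadow] <- base[shadow] * 0.30

    # --- neurovascular bundle ----------------------------------------------
    r_a <- config$artery_diam_mm * mm / 2
    b_v <- config$vein_minor_mm * mm / 2          # vein minor semi-axis (y)
    a_v <- b_v * stats::runif(1, 1.25, 1.55)      # compressed oval: wider
    r_n <- config$nerve_diam_mm * mm / 2
    depth <- boundary + stats::runif(1, 0.06, 0.16) * S
    side <- sample(c(-1, 1), 1)                   # right- or left-leg view
    xa <- S / 2 + stats::runif(1, -0.10, 0.10) * S
    xv <- xa + side * (r_a + a_v + stats::runif(1, 0.4, 1.0) * r_a)
    xn <- xa - side * (r_a + r_n + stats::runif(1, 0.3, 0.8) * r_a)
    yv <- depth + stats::runif(1, -0.4, 0.4) * r_a
    yn <- depth + stats::runif(1, -0.4, 0.4) * r_a
    clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
    xa <- clamp(xa, r_a + 3, S - r_a - 3)
    xv <- clamp(xv, a_v + 3, S - a_v - 3)
    xn <- clamp(xn, r_n + 3, S - r_n - 3)
    ya <- clamp(depth, r_a + 3, S - r_a - 3)
    yv <- clamp(yv, b_v + 3, S - b_v - 3)
    yn <- clamp(yn, r_n + 3, S - r_n - 3)

    artery_mask <- (X - xa)^2 + (Y - ya)^2 <= r_a^2
    vein_mask <- ((X - xv) / a_v)^2 + ((Y - yv) / b_v)^2 <= 1
    nerve_mask <- (X - xn)^2 + (Y - yn)^2 <= r_n^2
    base[vein_mask] <- iv$vein
    base[nerve_mask] <- iv$nerve
    # honeycomb-like bright stipple inside the nerve bundle
    n_dot <- max(4L, round(r_n))
    dth <- stats::runif(n_dot, 0, 2 * pi)
    drr <- sqrt(stats::runif(n_dot)) * (r_n - 1.5)
    for (k in seq_len(n_dot)) {
      d2 <- (X - (xn + drr[k] * cos(dth[k])))^2 +
            (Y - (yn + drr[k] * sin(dth[k])))^2
      dot <- d2 <= (0.12 * r_n)^2
      base[dot & nerve_mask] <- iv$nerve + 0.22
    }
    base[artery_mask] <- iv$artery
    D_a <- sqrt((X - xa)^2 + (Y - ya)^2)
    base[abs(D_a - r_a) <= 1.2] <- iv$artery_rim

    # --- shrapnel rod -------------------------------------------------------
    shrapnel_present <- stats::runif(1) < config$shrapnel_prob
    shrapnel_mask <- NULL
    if (shrapnel_present) {
      feature_union <- artery_mask | vein_mask | nerve_mask
      L_px <- stats::runif(1, config$shrapnel_len_mm[1],
                           config$shrapnel_len_mm[2]) * mm
      Dm_px <- config$shrapnel_diam_mm * mm
      placed <- FALSE
      margin <- L_px / 2 + 3
      y_lo <- boundary * 0.5
      y_hi <- min(S - margin, S * 0.8)
      feasible <- margin < S - margin && y_lo < y_hi
      for (try in seq_len(if (feasible) config$max_place_retries else 0L)) {
        theta <- stats::runif(1, 0, pi)
        cx <- stats::runif(1, margin, S - margin)
        cy <- stats::runif(1, y_lo, y_hi)
        t_ax <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
        n_ax <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
        cand <- abs(t_ax) <= L_px / 2 & abs(n_ax) <= Dm_px / 2
        # keep a 2 px standoff from the neurovascular features
        grown <- abs(t_ax) <= L_px / 2 + 2 & abs(n_ax) <= Dm_px / 2 + 2
        if (!any(grown & feature_union) && any(cand)) {
          shrapnel_mask <- cand
          base[cand] <- iv$shrapnel
          if (config$shrapnel_shadow) {
            sh <- abs(n_ax) <= Dm_px / 2 & t_ax > L_px / 2
            base[sh & Y > cy] <- base[sh & Y > cy] * 0.5
          }
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place shrapnel without touching the vein/artery/",
             "nerve after ", config$max_place_retries, " retries")
    }

    # --- speckle, depth gain, log compression -------------------------------
    img <- base
    if (config$speckle_scale > 0) {
      sigma <- sqrt(2 / pi)              # Rayleigh with unit mean
      ray <- sigma * sqrt(-2 * log(stats::runif(S * S)))
      noise <- blur3(matrix(ray, S, S))
      img <- img * (1 + config$speckle_scale * (noise - 1))
    }
    img <- img * (1 - 0.15 * Y / S)      # mild depth-dependent attenuation
    img <- pmin(pmax(img, 0), 1)
    if (config$log_compression > 0) {
      a <- config$log_compression
      img <- log1p(a * img) / log1p(a)
    }

    masks <- list(vein = vein_mask, artery = artery_mask, nerve = nerve_mask)
    if (!is.null(shrapnel_mask)) masks$shrapnel <- shrapnel_mask
    boxes <- do.call(rbind, lapply(names(masks), function(cl)
      mask_to_box(masks[[cl]], cl)))
    pixels <- array(img, dim = c(S, S, 3))
    meta <- list(seed = seed, shrapnel_present = shrapnel_present,
                 split = NA_character_)
    if (keep_masks) meta$masks <- masks[boxes$class]
    structure(list(pixels = pixels, boxes = boxes, meta = meta),
              class = "phantom_image")
  })
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom_image %dx%d, %d boxes (%s), seed %s\n",
              dim(x$pixels)[1], dim(x$pixels)[2], nrow(x$boxes),
              paste(x$boxes$class, collapse = ", "),
              format(x$meta$seed)))
  invisible(x)
}

#' Generate a dataset of annotated phantom images
#'
#' @param n number of images.
#' @param config a [phantom_config()].
#' @param seed base seed; image `i` uses an independent stream derived from
#'   `seed` and `i`.
#' @param keep_masks see [generate_phantom()].
#' @return list of `phantom_image` objects.
#' @export
generate_dataset <- function(n, config = phantom_config(), seed = 1,
                             keep_masks = FALSE) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i)
    generate_phantom(config, seed = seeds[i], keep_masks = keep_masks))
}
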