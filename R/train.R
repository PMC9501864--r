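#' Training configuration
#'
#' Defaults follow the published training recipe: SGD with momentum,
#' 125 epochs, batch size 16, L2 regularization 0.0005, base learning rate
#' 0.001 with a 1000-iteration quartic warmup, an IoU penalty threshold of
#' 0.5 and validation every 79 iterations. `max_iters` caps the run for
#' CPU-scale experiments.
#'
#' @param epochs passes over the training set.
#' @param batch_size images per iteration.
#' @param base_lr learning rate reached at the end of warmup.
#' @param warmup_iters warmup length in iterations.
#' @param momentum SGDM momentum coefficient.
#' @param l2_reg L2 regularization on convolution weights.
#' @param iou_penalty_threshold predicted boxes overlapping any ground truth
#'   at an IoU at or above this are excused from the no-object penalty.
#' @param val_frequency iterations between validation-loss evaluations.
#' @param lambda_coord,lambda_noobj,lambda_class loss-term weights.
#' @param augment augment training samples (validation/test never are).
#' @param augment_rotation include the random rotation in augmentation;
#'   disabling it keeps flips and scaling only (the CPU-scale profile does
#'   this, since orientation invariance is not learnable at that budget).
#' @param keep_best when a validation set is supplied, restore the
#'   parameters with the lowest validation loss at the end of the run.
#' @param post_warmup learning rate after warmup: `"constant"` (default)
#'   holds `base_lr`; `"decay"` applies a quartic slowdown
#'   `base_lr * (warmup_iters / iteration)^4`.
#' @param max_iters hard iteration cap (`Inf` = run all epochs).
#' @param seed seed for shuffling, augmentation and weight updates.
#' @param verbose print a line every `val_frequency` iterations.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 125, batch_size = 16, base_lr = 0.001,
                         warmup_iters = 1000, momentum = 0.9, l2_reg = 5e-4,
                         iou_penalty_threshold = 0.5, val_frequency = 79,
                         lambda_coord = 5, lambda_noobj = 0.5,
                         lambda_class = 1, augment = TRUE,
                         augment_rotation = TRUE, keep_best = TRUE,
                         post_warmup = c("constant", "decay"),
                         max_iters = Inf, seed = 1, verbose = FALSE) {
  post_warmup <- match.arg(post_warmup)
  stopifnot(epochs > 0, batch_size > 0, base_lr > 0, warmup_iters > 0,
            momentum >= 0, l2_reg >= 0,
            iou_penalty_threshold > 0, iou_penalty_threshold < 1,
            val_frequency > 0)
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a training iteration
#'
#' During warmup the rate ramps up as
#' `base_lr * (iteration / warmup_iters)^4`, reaching exactly `base_lr` at
#' `iteration = warmup_iters`; afterwards it is held constant (or, with
#' `post_warmup = "decay"`, slowed down by the mirrored quartic
#' `base_lr * (warmup_iters / iteration)^4`). The schedule is continuous and
#' monotone nondecreasing over the warmup.
#'
#' @param iteration training iteration, `>= 1`.
#' @param config a [train_config()].
#' @export
lr_schedule <- function(iteration, config = train_config()) {
  stopifnot(all(iteration >= 1))
  base <- config$base_lr
  wu <- config$warmup_iters
  ifelse(iteration <= wu,
         base * (iteration / wu)^4,
         if (config$post_warmup == "constant") base
         else base * (wu / iteration)^4)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
logit <- function(p) log(p / (1 - p))
# numerically stable log(1 + exp(z))
softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Assign each ground-truth box to its best-shape anchor (over both heads).
# Returns a data frame with the head, anchor index within the head, grid
# cell (1-based row/col) and regression targets.
encode_targets <- function(model, boxes) {
  if (nrow(boxes) == 0)
    return(data.frame(head = character(0), a = integer(0), row = integer(0),
                      col = integer(0), tx = numeric(0), ty = numeric(0),
                      tw = numeric(0), th = numeric(0), cls = integer(0),
                      size_w = numeric(0)))
  anc <- model$anchors$anchors
  n_fine <- nrow(model$anchors$fine)
  si <- shape_iou(cbind(boxes$w, boxes$h), anc)
  best <- max.col(si, ties.method = "first")
  head <- ifelse(best <= n_fine, "fine", "coarse")
  a <- ifelse(best <= n_fine, best, best - n_fine)
  stride <- model$strides[head]
  grid <- model$input_size %/% stride
  cx <- boxes$x + boxes$w / 2
  cy <- boxes$y + boxes$h / 2
  col <- pmin(pmax(floor(cx / stride) + 1, 1), grid)
  row <- pmin(pmax(floor(cy / stride) + 1, 1), grid)
  aw <- anc[best, 1]; ah <- anc[best, 2]
  data.frame(head = head, a = as.integer(a), row = as.integer(row),
             col = as.integer(col),
             tx = cx / stride - (col - 1), ty = cy / stride - (row - 1),
             tw = log(boxes$w / aw), th = log(boxes$h / ah),
             cls = match(boxes$class, model$class_names),
             # small boxes get extra coordinate-loss weight (2 - area frac.)
             size_w = 2 - (boxes$w * boxes$h) / model$input_size^2,
             stringsAsFactors = FALSE)
}

# Loss and gradient w.r.t. the raw outputs of one head, for a batch.
# z: (g, g, A*(5+C), N); truths: list of box data frames (one per image);
# assigns: list of encode_targets() frames filtered to this head.
head_loss <- function(z, assigns, truths, anchors_head, stride, n_classes,
                      cfg) {
  d <- dim(z)
  g <- d[1]; N <- d[4]
  A <- nrow(anchors_head)
  nc <- 5 + n_classes
  obj_ch <- (seq_len(A) - 1) * nc + 5
  dz <- array(0, dim = d)

  # no-object penalty everywhere, minus assigned and excused predictors
  z_obj <- z[, , obj_ch, , drop = FALSE]
  s_obj <- sigmoid(z_obj)
  noobj_w <- array(cfg$lambda_noobj, dim = dim(z_obj))
  for (n in seq_len(N)) {
    tb <- truths[[n]]
    if (nrow(tb) == 0) next
    dec <- decode_head_grid(z[, , , n, drop = TRUE], anchors_head, stride,
                            n_classes, g, A)
    excused <- rep(FALSE, nrow(dec))
    for (t in seq_len(nrow(tb))) {
      ix <- pmax(0, pmin(dec$x + dec$w, tb$x[t] + tb$w[t]) -
                   pmax(dec$x, tb$x[t]))
      iy <- pmax(0, pmin(dec$y + dec$h, tb$y[t] + tb$h[t]) -
                   pmax(dec$y, tb$y[t]))
      inter <- ix * iy
      un <- dec$w * dec$h + tb$w[t] * tb$h[t] - inter
      excused <- excused | (inter / pmax(un, 1e-9) >= cfg$iou_penalty_threshold)
    }
    # dec rows are ordered (row, col, anchor); map into the (g, g, A) block
    w_n <- noobj_w[, , , n]
    w_n[array(excused, dim = c(g, g, A))] <- 0
    noobj_w[, , , n] <- w_n
  }
  for (n in seq_len(N)) {
    asn <- assigns[[n]]
    if (nrow(asn) > 0)
      noobj_w[cbind(asn$row, asn$col, asn$a, n)] <- 0
  }
  loss <- sum(noobj_w * softplus(z_obj))           # BCE with target 0
  dz[, , obj_ch, ] <- noobj_w * s_obj

  # assigned predictors: box regression, objectness 1, class one-hot
  for (n in seq_len(N)) {
    asn <- assigns[[n]]
    if (nrow(asn) == 0) next
    for (i in seq_len(nrow(asn))) {
      base <- (asn$a[i] - 1) * nc
      r <- asn$row[i]; cl <- asn$col[i]
      zxy <- z[r, cl, base + 1:2, n]
      sxy <- sigmoid(zxy)
      txy <- c(asn$tx[i], asn$ty[i])
      zwh <- z[r, cl, base + 3:4, n]
      twh <- c(asn$tw[i], asn$th[i])
      lc <- cfg$lambda_coord * asn$size_w[i]
      loss <- loss + lc * (sum((sxy - txy)^2) + sum((zwh - twh)^2))
      dz[r, cl, base + 1:2, n] <- dz[r, cl, base + 1:2, n] +
        lc * 2 * (sxy - txy) * sxy * (1 - sxy)
      dz[r, cl, base + 3:4, n] <- dz[r, cl, base + 3:4, n] +
        lc * 2 * (zwh - twh)
      zo <- z[r, cl, base + 5, n]
      loss <- loss + softplus(zo) - zo               # BCE with target 1
      dz[r, cl, base + 5, n] <- dz[r, cl, base + 5, n] + sigmoid(zo) - 1
      if (n_classes > 0) {
        y <- as.numeric(seq_len(n_classes) == asn$cls[i])
        zc <- z[r, cl, base + 5 + seq_len(n_classes), n]
        loss <- loss + cfg$lambda_class * sum(softplus(zc) - y * zc)
        dz[r, cl, base + 5 + seq_len(n_classes), n] <-
          dz[r, cl, base + 5 + seq_len(n_classes), n] +
          cfg$lambda_class * (sigmoid(zc) - y)
      }
    }
  }
  list(loss = loss, dz = dz)
}

# Decode every predictor of one head (single image) into pixel boxes.
# Row order: grid row fastest, then grid column, then anchor.
decode_head_grid <- function(z, anchors_head, stride, n_classes, g, A) {
  nc <- 5 + n_classes
  rows <- rep(seq_len(g), times = g * A)
  cols <- rep(rep(seq_len(g), each = g), times = A)
  aa <- rep(seq_len(A), each = g * g)
  base <- (aa - 1) * nc
  idx <- function(k) cbind(rows, cols, base + k)
  tx <- sigmoid(z[idx(1)])
  ty <- sigmoid(z[idx(2)])
  bw <- anchors_head[aa, 1] * exp(pmin(z[idx(3)], 8))
  bh <- anchors_head[aa, 2] * exp(pmin(z[idx(4)], 8))
  cx <- (cols - 1 + tx) * stride
  cy <- (rows - 1 + ty) * stride
  out <- data.frame(x = cx - bw / 2, y = cy - bh / 2, w = bw, h = bh,
                    obj = sigmoid(z[idx(5)]))
  if (n_classes > 0) {
    cls_s <- vapply(seq_len(n_classes),
                    function(c) sigmoid(z[idx(5 + c)]), numeric(g * g * A))
    cls_s <- matrix(cls_s, ncol = n_classes)
    out$cls <- max.col(cls_s, ties.method = "first")
    out$cls_score <- cls_s[cbind(seq_len(nrow(cls_s)), out$cls)]
  }
  out
}

# Total loss (and raw-output gradients) for a batch of annotated images.
batch_loss <- function(model, images, cfg, training = TRUE,
                       with_grads = TRUE) {
  x <- batch_from_images(images)
  raw <- model_forward_raw(model, x, training = training)
  N <- length(images)
  assigns <- lapply(images, function(im) encode_targets(model, im$boxes))
  truths <- lapply(images, `[[`, "boxes")
  per_head <- lapply(c("fine", "coarse"), function(h) {
    z <- raw[[h]]
    asn_h <- lapply(assigns, function(a) a[a$head == h, , drop = FALSE])
    anc <- model$anchors[[h]]
    head_loss(z, asn_h, truths, anc, model$strides[[h]], model$n_classes,
              cfg)
  })
  loss <- (per_head[[1]]$loss + per_head[[2]]$loss) / N
  out <- list(loss = loss)
  if (with_grads) {
    dout <- list(per_head[[1]]$dz / N, per_head[[2]]$dz / N)
    names(dout) <- model$outputs[c("fine", "coarse")]
    out$grads <- net_backward(model, raw$fw, dout)
  }
  out
}

#' Train the detector
#'
#' Mini-batch SGD with momentum over the YOLO-style loss: weighted squared
#' error on the assigned predictors' box offsets, binary cross-entropy on
#' objectness (predictors whose decoded box overlaps a ground truth at IoU at
#' or above the penalty threshold are excused from the no-object term) and
#' binary cross-entropy on class scores. Each ground truth is assigned to the
#' predictor whose anchor shape matches it best. Augmentation is applied to
#' training samples only; anchor estimation is expected to have used training
#' boxes only. The run is deterministic for a fixed config seed.
#'
#' @param model a [build_model()] network. Use the returned model: with
#'   `keep_best` the returned object carries the best-validation parameters.
#' @param train_set,val_set lists of annotated images (`pixels` + `boxes`).
#' @param config a [train_config()].
#' @return list with `model` and `history` (data frame `iteration`, `epoch`,
#'   `loss`, `lr`, `val_loss` -- `NA` except at validation iterations).
#' @export
train <- function(model, train_set, val_set = NULL, config = train_config()) {
  stopifnot(length(train_set) > 0)
  seen <- unique(unlist(lapply(train_set, function(im) im$boxes$class)))
  missing <- setdiff(model$class_names, seen)
  if (length(missing) > 0)
    warning("classes absent from the training set: ",
            paste(missing, collapse = ", "))
  history <- list()
  it <- 0L
  best <- list(loss = Inf, params = NULL)
  snapshot <- function() lapply(model$nodes, function(n)
    if (is.null(n$par)) NULL else as.list(n$par))
  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(train_set))
      starts <- seq(1, length(ord), by = config$batch_size)
      for (s in starts) {
        if (it >= config$max_iters) break
        it <- it + 1L
        idx <- ord[s:min(s + config$batch_size - 1, length(ord))]
        batch <- train_set[idx]
        if (config$augment)
          batch <- lapply(batch, augment_sample,
                          angle = if (config$augment_rotation) NULL else 0)
        bl <- batch_loss(model, batch, config, training = TRUE)
        lr <- lr_schedule(it, config)
        net_update(model, bl$grads, lr, config$momentum, config$l2_reg)
        val_loss <- NA_real_
        if (!is.null(val_set) && it %% config$val_frequency == 0) {
          val_loss <- batch_loss(model, val_set, config, training = FALSE,
                                 with_grads = FALSE)$loss
          if (isTRUE(config$keep_best) && val_loss < best$loss)
            best <- list(loss = val_loss, params = snapshot())
        }
        history[[it]] <- data.frame(iteration = it, epoch = epoch,
                                    loss = bl$loss, lr = lr,
                                    val_loss = val_loss)
        if (config$verbose && it %% config$val_frequency == 0)
          message(sprintf("iter %d (epoch %d): loss %.4f lr %.2e", it,
                          epoch, bl$loss, lr))
      }
      if (it >= config$max_iters) break
    }
  })
  if (!is.null(best$params)) {
    for (i in seq_along(model$nodes)) {
      if (is.null(best$params[[i]])) next
      model$nodes[[i]]$par <- list2env(best$params[[i]],
                                       parent = emptyenv())
    }
  }
  list(model = model, history = do.call(rbind, history),
       best_val_loss = if (is.finite(best$loss)) best$loss else NA_real_)
}
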