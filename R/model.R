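#' Build the shrapnel detector network
#'
#' A SqueezeNet-style backbone with two single-stage (YOLO-style) output
#' heads. The stem is a 3x3/stride-2 convolution with ReLU followed by max
#' pooling; four shared Fire blocks feed a five-Fire-block path on the
#' class/detection side. A Fire block squeezes with a 1x1 convolution (ReLU)
#' and expands through parallel 1x1 and 3x3 convolutions whose outputs are
#' depth-concatenated. The fine head (stride 16) reads the last Fire
#' concatenation through a conv + batch-norm + ReLU block; the coarse head
#' (stride 32) fuses that concatenation -- downsampled by a feature-resizing
#' conv block -- with the pooled second-to-last Fire block, then applies a
#' final concatenation and conv block. Each head ends in a linear 1x1
#' convolution emitting `n_anchors x (5 + n_classes)` channels per grid cell
#' (4 box offsets, objectness, class scores).
#'
#' Channel widths follow the SqueezeNet v1.1 trunk scaled by `width`; the
#' reduced-width profile is the package's CPU-scale test harness.
#'
#' @param anchors an [estimate_anchors()] `anchor_set`; its `fine` anchors go
#'   to the stride-16 head and its `coarse` anchors to the stride-32 head.
#' @param input_size square input side, must be divisible by 32.
#' @param n_classes number of object classes (1 for shrapnel-only, 4 with
#'   vein/artery/nerve).
#' @param width channel width multiplier.
#' @param class_names labels, length `n_classes`.
#' @param seed seed for weight initialisation.
#' @return A `shrapod_model`.
#' @export
build_model <- function(anchors, input_size = 512, n_classes = 4,
                        width = 1,
                        class_names = c("shrapnel", "vein", "artery",
                                        "nerve")[seq_len(n_classes)],
                        seed = 1) {
  if (input_size %% 32 != 0)
    stop("input_size must be divisible by the coarse head stride (32)")
  stopifnot(inherits(anchors, "anchor_set"),
            length(class_names) == n_classes)
  wmul <- function(c) max(2L, as.integer(round(c * width)))
  a_fine <- nrow(anchors$fine)
  a_coarse <- nrow(anchors$coarse)
  out_per_anchor <- 5 + n_classes

  with_seed(seed, {
    nodes <- list()
    add <- function(node) nodes[[length(nodes) + 1]] <<- node
    fire <- function(name, input, in_c, s, e) {
      add(new_conv(paste0(name, "_s"), input, in_c, s, k = 1))
      add(new_conv(paste0(name, "_e1"), paste0(name, "_s"), s, e, k = 1))
      add(new_conv(paste0(name, "_e3"), paste0(name, "_s"), s, e, k = 3))
      add(new_concat(paste0(name, "_cat"),
                     c(paste0(name, "_e1"), paste0(name, "_e3")), c(e, e)))
      2 * e
    }

    c1 <- wmul(64)
    add(new_conv("conv1", "input", 3, c1, k = 3, stride = 2))
    add(new_pool("pool1", "conv1", c1))                       # stride 4
    c2 <- fire("fire2", "pool1", c1, wmul(16), wmul(64))
    c3 <- fire("fire3", "fire2_cat", c2, wmul(16), wmul(64))
    add(new_pool("pool3", "fire3_cat", c3))                   # stride 8
    c4 <- fire("fire4", "pool3", c3, wmul(32), wmul(128))
    c5 <- fire("fire5", "fire4_cat", c4, wmul(32), wmul(128))
    add(new_pool("pool5", "fire5_cat", c5))                   # stride 16
    c6 <- fire("fire6", "pool5", c5, wmul(48), wmul(192))
    c7 <- fire("fire7", "fire6_cat", c6, wmul(48), wmul(192))
    c8 <- fire("fire8", "fire7_cat", c7, wmul(64), wmul(256))
    c9 <- fire("fire9", "fire8_cat", c8, wmul(64), wmul(256))
    c10 <- fire("fire10", "fire9_cat", c9, wmul(64), wmul(256))

    # fine head, stride 16: conv block (conv + BN + ReLU) then linear 1x1
    cf <- wmul(128)
    add(new_conv("head1_conv", "fire10_cat", c10, cf, k = 3, act = "linear"))
    add(new_bn("head1_bn", "head1_conv", cf))
    add(new_relu("head1_relu", "head1_bn", cf))
    add(new_conv("head1_out", "head1_relu", cf,
                 a_fine * out_per_anchor, k = 1, act = "linear"))

    # coarse head, stride 32: feature-resizing conv block on the last Fire
    # concatenation, fused with the pooled second-to-last Fire block
    add(new_conv("resize_conv", "fire10_cat", c10, cf, k = 3, stride = 2,
                 act = "linear"))
    add(new_bn("resize_bn", "resize_conv", cf))
    add(new_relu("resize_relu", "resize_bn", cf))
    add(new_pool("skip_pool", "fire9_cat", c9))
    add(new_concat("head2_cat", c("resize_relu", "skip_pool"), c(cf, c9)))
    add(new_conv("head2_conv", "head2_cat", cf + c9, cf, k = 3,
                 act = "linear"))
    add(new_bn("head2_bn", "head2_conv", cf))
    add(new_relu("head2_relu", "head2_bn", cf))
    add(new_conv("head2_out", "head2_relu", cf,
                 a_coarse * out_per_anchor, k = 1, act = "linear"))

    structure(list(nodes = nodes,
                   outputs = c(fine = "head1_out", coarse = "head2_out"),
                   strides = c(fine = 16L, coarse = 32L),
                   anchors = anchors,
                   input_size = as.integer(input_size),
                   n_classes = as.integer(n_classes),
                   class_names = class_names,
                   width = width),
              class = "shrapod_model")
  })
}

#' @export
print.shrapod_model <- function(x, ...) {
  n_par <- sum(vapply(x$nodes, function(node) {
    if (is.null(node$par)) return(0)
    if (node$op == "conv") length(node$par$W) + length(node$par$b)
    else length(node$par$gamma) + length(node$par$beta)
  }, numeric(1)))
  cat(sprintf(
    "shrapod_model: input %dx%dx3, %d classes, width %.2f, %s parameters\n",
    x$input_size, x$input_size, x$n_classes, x$width,
    format(n_par, big.mark = ",")))
  cat(sprintf("  heads: stride 16 (%d anchors), stride 32 (%d anchors)\n",
              nrow(x$anchors$fine), nrow(x$anchors$coarse)))
  invisible(x)
}

# Grid sizes of the two heads.
model_grids <- function(model) model$input_size %/% model$strides

# Stack a list of images into the (H, W, C, N) batch array the network eats.
batch_from_images <- function(images) {
  S <- dim(images[[1]]$pixels)[1]
  x <- array(0, dim = c(S, S, 3, length(images)))
  for (i in seq_along(images)) x[, , , i] <- images[[i]]$pixels
  x
}

# Raw head outputs for a batch: list(fine = (g, g, A*(5+C), N), coarse = ...).
model_forward_raw <- function(model, x, training = FALSE) {
  fw <- net_forward(model, x, training)
  list(fw = fw,
       fine = fw$acts[[model$outputs["fine"]]],
       coarse = fw$acts[[model$outputs["coarse"]]])
}
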