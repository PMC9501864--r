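test_that("head grids are integer downsamplings at strides 16 and 32", {
  m <- tiny_model(input_size = 64)
  x <- array(0, dim = c(64, 64, 3, 1))
  raw <- shrapod:::model_forward_raw(m, x)
  A_f <- nrow(m$anchors$fine); A_c <- nrow(m$anchors$coarse)
  expect_equal(dim(raw$fine), c(4, 4, A_f * 9, 1))     # 64 / 16
  expect_equal(dim(raw$coarse), c(2, 2, A_c * 9, 1))   # 64 / 32
  expect_true(all(is.finite(raw$fine)), all(is.finite(raw$coarse)))
  expect_equal(unname(shrapod:::model_grids(m)), c(4, 2))
  # 512-input geometry follows the same arithmetic
  expect_equal(512 %/% m$strides, c(fine = 32, coarse = 16))
  expect_error(build_model(estimate_anchors(tiny_shapes(), k = 2),
                           input_size = 100), "divisible")
})

test_that("class count only changes the output channel width", {
  anc <- estimate_anchors(tiny_shapes(), k = 4, seed = 1)
  m1 <- build_model(anc, input_size = 64, n_classes = 1, width = 0.12,
                    class_names = "shrapnel")
  m4 <- build_model(anc, input_size = 64, n_classes = 4, width = 0.12)
  out1 <- Filter(function(n) n$name == "head1_out", m1$nodes)[[1]]
  out4 <- Filter(function(n) n$name == "head1_out", m4$nodes)[[1]]
  expect_equal(out1$out_c, nrow(anc$fine) * 6)
  expect_equal(out4$out_c, nrow(anc$fine) * 9)
  nm1 <- vapply(m1$nodes, `[[`, character(1), "name")
  nm4 <- vapply(m4$nodes, `[[`, character(1), "name")
  expect_identical(nm1, nm4)
})

test_that("every Fire block squeezes then expands through parallel convs", {
  m <- tiny_model()
  nodes <- setNames(m$nodes, vapply(m$nodes, `[[`, character(1), "name"))
  for (f in paste0("fire", 2:10)) {
    expect_equal(nodes[[paste0(f, "_s")]]$k, 1)
    expect_equal(nodes[[paste0(f, "_e1")]]$k, 1)
    expect_equal(nodes[[paste0(f, "_e3")]]$k, 3)
    expect_equal(nodes[[paste0(f, "_e1")]]$input, paste0(f, "_s"))
    expect_equal(nodes[[paste0(f, "_e3")]]$input, paste0(f, "_s"))
    expect_setequal(nodes[[paste0(f, "_cat")]]$input,
                    paste0(f, c("_e1", "_e3")))
  }
})

test_that("encoding a ground-truth box and decoding recovers it exactly", {
  m <- tiny_model(input_size = 96, width = 0.25)
  boxes <- bbox_bind(bbox(12.5, 20.25, 30, 22, "artery"),
                     bbox(60, 50, 9, 14, "shrapnel"),
                     bbox(30.7, 61.2, 14.5, 11.9, "vein"))
  enc <- shrapod:::encode_targets(m, boxes)
  expect_equal(nrow(enc), 3)
  lg <- function(p) log(p / (1 - p))
  for (h in unique(enc$head)) {
    e <- enc[enc$head == h, ]
    g <- 96 / m$strides[[h]]
    A <- nrow(m$anchors[[h]])
    z <- array(0, dim = c(g, g, A * 9))
    for (i in seq_len(nrow(e))) {
      base <- (e$a[i] - 1) * 9
      z[e$row[i], e$col[i], base + 1:4] <-
        c(lg(e$tx[i]), lg(e$ty[i]), e$tw[i], e$th[i])
    }
    dec <- shrapod:::decode_head_grid(z, m$anchors[[h]], m$strides[[h]],
                                      4, g, A)
    for (i in seq_len(nrow(e))) {
      pos <- (e$a[i] - 1) * g * g + (e$col[i] - 1) * g + e$row[i]
      orig <- boxes[enc$head == h, ][i, ]
      expect_equal(unlist(dec[pos, c("x", "y", "w", "h")]),
                   unlist(orig[c("x", "y", "w", "h")]),
                   tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("backpropagated gradients match numeric differentiation", {
  imgs <- lapply(1:2, random_annotated)
  m <- tiny_model()
  cfg <- train_config(seed = 1)
  bl <- shrapod:::batch_loss(m, imgs, cfg, training = TRUE)
  nodes <- setNames(m$nodes, vapply(m$nodes, `[[`, character(1), "name"))
  set.seed(2)
  for (spec in list(c("conv1", "W"), c("fire4_e3", "W"), c("head1_bn", "gamma"),
                    c("head2_conv", "W"), c("fire9_s", "b"))) {
    node <- nodes[[spec[1]]]
    field <- spec[2]
    g <- bl$grads[[spec[1]]][[field]]
    for (i in sample(length(node$par[[field]]), 2)) {
      eps <- 1e-5
      orig <- node$par[[field]][i]
      node$par[[field]][i] <- orig + eps
      lp <- shrapod:::batch_loss(m, imgs, cfg, training = TRUE,
                                 with_grads = FALSE)$loss
      node$par[[field]][i] <- orig - eps
      lm <- shrapod:::batch_loss(m, imgs, cfg, training = TRUE,
                                 with_grads = FALSE)$loss
      node$par[[field]][i] <- orig
      num <- (lp - lm) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the quartic warmup schedule matches its closed form", {
  cfg <- train_config()
  expect_equal(lr_schedule(1000, cfg), 0.001)
  expect_equal(lr_schedule(500, cfg), 0.001 * 0.5^4)   # 6.25e-5
  expect_equal(lr_schedule(1, cfg), 1e-15)
  expect_equal(lr_schedule(5000, cfg), 0.001)          # constant afterwards
  # monotone nondecreasing over warmup, continuous at the boundary
  lrs <- lr_schedule(1:1000, cfg)
  expect_true(all(diff(lrs) >= 0))
  expect_equal(lrs[1000], cfg$base_lr)
  expect_error(lr_schedule(0, cfg))
  # optional post-warmup quartic slowdown
  dcfg <- train_config(post_warmup = "decay")
  expect_equal(lr_schedule(1000, dcfg), 0.001)
  expect_equal(lr_schedule(2000, dcfg), 0.001 / 16)
  expect_true(all(diff(lr_schedule(1000:1100, dcfg)) < 0))
})

test_that("training reduces the loss and is seed-deterministic", {
  imgs <- lapply(1:3, random_annotated)
  cfg <- train_config(epochs = 50, batch_size = 3, base_lr = 0.002,
                      warmup_iters = 10, augment = FALSE, max_iters = 25,
                      seed = 3)
  m1 <- tiny_model(seed = 7)
  r1 <- suppressWarnings(train(m1, imgs, config = cfg))
  expect_equal(nrow(r1$history), 25)
  expect_lt(tail(r1$history$loss, 1), 0.5 * r1$history$loss[1])
  m2 <- tiny_model(seed = 7)
  r2 <- suppressWarnings(train(m2, imgs, config = cfg))
  expect_identical(r1$history$loss, r2$history$loss)
})

test_that("training warns when a class is absent from the training set", {
  imgs <- lapply(1:2, random_annotated)
  for (i in seq_along(imgs)) imgs[[i]]$boxes$class <- "vein"
  m <- tiny_model()
  expect_warning(
    train(m, imgs, config = train_config(epochs = 1, batch_size = 2,
                                         augment = FALSE, max_iters = 1)),
    "absent")
})

test_that("prediction thresholds, NMS and clipping behave as specified", {
  m <- tiny_model()
  img <- random_annotated(1)
  # a confidence threshold of 1 forces an empty detection list
  expect_equal(nrow(predict_image(m, img, conf_threshold = 1)), 0)
  # untrained model, permissive threshold: finite boxes clipped to frame
  d <- predict_image(m, img, conf_threshold = 0)
  expect_true(all(is.finite(as.matrix(d[, c("x", "y", "w", "h")]))))
  expect_true(all(d$x >= 0 & d$y >= 0 & d$x + d$w <= 64 & d$y + d$h <= 64))
  expect_true(all(d$score >= 0 & d$score <= 1))
  # NMS keeps only the higher-confidence of two identical boxes
  two <- bbox_bind(bbox(10, 10, 20, 20, "vein", 0.9),
                   bbox(10, 10, 20, 20, "vein", 0.8))
  kept <- nms(two, nms_iou = 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$score, 0.9)
  # different classes are never suppressed against each other
  mixed <- bbox_bind(bbox(10, 10, 20, 20, "vein", 0.9),
                     bbox(10, 10, 20, 20, "artery", 0.8))
  expect_equal(nrow(nms(mixed, 0.5)), 2)
})
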