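test_that("iou matches direct area arithmetic and its invariances", {
  expect_equal(iou(bbox(3, 4, 10, 12), bbox(3, 4, 10, 12)), 1)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(50, 50, 5, 5)), 0)
  expect_equal(iou(bbox(0, 0, 10, 10), bbox(5, 0, 10, 10)), 1 / 3)
  expect_error(iou(bbox(1, 1, 0, 0), bbox(2, 2, 0, 0)), "zero-area")

  set.seed(42)
  for (i in 1:50) {
    a <- bbox(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 40), runif(1, 1, 40))
    b <- bbox(runif(1, 0, 50), runif(1, 0, 50), runif(1, 1, 40), runif(1, 1, 40))
    v <- iou(a, b)
    expect_equal(v, oracle_iou(a, b))
    expect_equal(v, iou(b, a))            # symmetric
    expect_gte(v, 0); expect_lte(v, 1)
    shift <- function(z, dx, dy) bbox(z$x + dx, z$y + dy, z$w, z$h)
    expect_equal(iou(shift(a, 7, -3), shift(b, 7, -3)), v)  # translation
    scale <- function(z, s) bbox(z$x * s, z$y * s, z$w * s, z$h * s)
    expect_equal(iou(scale(a, 2.5), scale(b, 2.5)), v)      # scale-covariant
  }
})

test_that("iou equals 1 only for identical boxes", {
  a <- bbox(0, 0, 10, 10)
  expect_lt(iou(a, bbox(0, 0, 10, 10.001)), 1)
  expect_lt(iou(a, bbox(0.5, 0, 10, 10)), 1)
})

test_that("match_image implements the IoU-gated counting rules", {
  gt <- bbox(10, 10, 20, 20, "vein")
  # perfect match
  m <- match_image(bbox(10, 10, 20, 20, "vein", 0.9), gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(m$iou_sample, 1)
  # two high-IoU predictions on one ground truth: surplus is a false positive
  p2 <- bbox_bind(bbox(10, 10, 20, 20, "vein", 0.9),
                  bbox(11, 10, 20, 20, "vein", 0.8))
  m <- match_image(p2, gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 1, 0))
  # prediction without ground truth, and ground truth without prediction
  m <- match_image(bbox(10, 10, 20, 20, "vein", 0.9), empty_boxes())
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 1, 0))
  expect_equal(m$iou_sample, 0)
  m <- match_image(empty_boxes(), gt)
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 1))
  expect_equal(m$iou_sample, 0)  # missed ground truth contributes a 0 IoU
  # empty image contributes no mIoU sample
  m <- match_image(empty_boxes(), empty_boxes())
  expect_true(is.na(m$iou_sample))
  # mixed classes rejected
  expect_error(match_image(bbox(0, 0, 5, 5, "vein", 0.5),
                           bbox(0, 0, 5, 5, "artery")), "single class")
})

test_that("match_image conserves counts and agrees with the greedy oracle", {
  set.seed(7)
  for (i in 1:40) {
    sc <- random_scene(n_img = 1)
    m <- match_image(sc$preds, sc$truths)
    o <- oracle_match(sc$preds, sc$truths)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
    expect_equal(sort(m$gt_iou), sort(o$gt_iou))
    expect_equal(m$tp + m$fn, nrow(sc$truths))
    expect_equal(m$tp + m$fp, nrow(sc$preds))
  }
})

test_that("average precision: closed cases and the cut-point oracle", {
  # perfect detector
  gt <- bbox(10, 10, 20, 20, "vein"); gt$image_id <- 1
  pd <- bbox(10, 10, 20, 20, "vein", 0.9); pd$image_id <- 1
  expect_equal(pr_curve_and_ap(pd, gt)$ap, 1)
  # no predictions
  none <- empty_boxes(); none$image_id <- integer(0)
  expect_equal(pr_curve_and_ap(none, gt)$ap, 0)
  # zero ground truths undefined
  expect_error(pr_curve_and_ap(pd, none), "undefined")

  # 3 ground truths; predictions (0.9 correct), (0.8 wrong), (0.7 correct):
  # cumulative PR points (1, 1/3), (1/2, 1/3), (2/3, 2/3); envelope area
  # = 1/3 * 1 + 1/3 * 2/3 = 5/9
  gts <- do.call(rbind, lapply(1:3, function(i) {
    b <- bbox(0, 0, 20, 20, "vein"); b$image_id <- i; b
  }))
  mk <- function(id, good, s) {
    b <- if (good) bbox(0, 0, 20, 20, "vein", s) else bbox(60, 60, 20, 20, "vein", s)
    b$image_id <- id; b
  }
  pds <- bbox_bind(mk(1, TRUE, 0.9), mk(2, FALSE, 0.8), mk(3, TRUE, 0.7))
  r <- pr_curve_and_ap(pds, gts)
  expect_equal(r$ap, 5 / 9)
  expect_equal(r$ap, oracle_ap(pds, gts))

  set.seed(11)
  for (i in 1:25) {
    sc <- random_scene(n_img = 3)
    if (nrow(sc$truths) == 0) next
    expect_equal(pr_curve_and_ap(sc$preds, sc$truths)$ap,
                 oracle_ap(sc$preds, sc$truths), tolerance = 1e-12)
  }
})

test_that("trapezoid AP integrates the raw curve", {
  gt <- bbox(10, 10, 20, 20, "vein"); gt$image_id <- 1
  pd <- bbox(10, 10, 20, 20, "vein", 0.9); pd$image_id <- 1
  expect_equal(pr_curve_and_ap(pd, gt, interpolation = "trapezoid")$ap, 1)
})

test_that("summarize_class reproduces hand-computed ratios", {
  mk_match <- function(tp, fp, fn, samples) {
    structure(list(tp = tp, fp = fp, fn = fn, gt_iou = numeric(0),
                   iou_sample = samples, pred_is_tp = logical(0),
                   ord = integer(0)), class = "match_result")
  }
  set.seed(5)
  for (i in 1:20) {
    tp <- sample(0:10, 1); fp <- sample(0:5, 1); fn <- sample(0:5, 1)
    s <- summarize_class(list(mk_match(tp, fp, fn, runif(1))), ap = 0.5,
                         class = "vein")
    if (tp + fp > 0) expect_equal(s$precision, tp / (tp + fp))
    else expect_true(is.na(s$precision))
    if (tp + fn > 0) expect_equal(s$recall, tp / (tp + fn))
    else expect_true(is.na(s$recall))
    if (!is.na(s$precision) && !is.na(s$recall) && s$precision + s$recall > 0)
      expect_equal(s$f1, 2 * s$precision * s$recall / (s$precision + s$recall))
    if (tp + fp + fn > 0) {
      expect_equal(s$pct_tp, 100 * tp / (tp + fp + fn))
      expect_equal(s$pct_tp + s$pct_fp + s$pct_fn, 100)
    }
  }
  # recall with no misses
  s <- summarize_class(list(mk_match(5, 0, 0, 1)), ap = 1, class = "vein")
  expect_equal(s$recall, 1)
})

test_that("mIoU is order-invariant and bounded by the max sample", {
  set.seed(9)
  mk_match <- function(sample) {
    structure(list(tp = 1, fp = 0, fn = 0, gt_iou = sample,
                   iou_sample = sample, pred_is_tp = TRUE, ord = 1L),
              class = "match_result")
  }
  samples <- runif(10)
  ms <- lapply(samples, mk_match)
  s1 <- summarize_class(ms, ap = 1, class = "vein")
  s2 <- summarize_class(ms[sample(10)], ap = 1, class = "vein")
  expect_equal(s1$miou, s2$miou)
  expect_lte(s1$miou, max(samples))
  expect_equal(s1$miou, mean(samples))
})

test_that("summarize_all averages columns and passes single rows through", {
  one <- summarize_class(list(structure(list(tp = 3, fp = 1, fn = 0,
                                             gt_iou = 0.8, iou_sample = 0.8,
                                             pred_is_tp = TRUE, ord = 1L),
                                        class = "match_result")),
                         ap = 0.9, class = "vein")
  out <- summarize_all(one)
  expect_equal(nrow(out), 2)
  expect_equal(out$miou[2], out$miou[1])
  expect_equal(out$ap[2], out$ap[1])
})
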