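test_that("midpoint adds half the width and height to the top-left corner", {
  expect_equal(unname(midpoint(bbox(10, 20, 30, 40))), c(25, 40))
  expect_equal(unname(midpoint(bbox(0, 0, 0, 0))), c(0, 0))
  # fractional midpoints are preserved, nothing is rounded
  expect_equal(unname(midpoint(bbox(100, 100, 51, 51))), c(125.5, 125.5))
})

test_that("pair_distance is the Euclidean distance", {
  expect_equal(pair_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(pair_distance(c(2.5, -1), c(2.5, -1)), 0)
  expect_equal(pair_distance(c(1, 1), c(4, 5)), 5)
})

make_dets <- function(shrap = bbox(0, 0, 10, 10, "shrapnel", 0.9),
                      vein = bbox(25, 35, 10, 10, "vein", 0.8),
                      artery = bbox(55, 75, 10, 10, "artery", 0.8),
                      nerve = bbox(1, 8, 10, 10, "nerve", 0.8)) {
  bbox_bind(shrap, vein, artery, nerve)
}

test_that("triage_image filters, selects best detections and measures", {
  dets <- make_dets()
  # drop the nerve: image is filtered out
  expect_null(triage_image(dets[dets$class != "nerve", ]))
  r <- triage_image(dets, image_id = "a")
  # shrapnel mid (5,5); vein mid (30,40); artery mid (60,80); nerve mid (6,13)
  expect_equal(r$d_vein, sqrt(25^2 + 35^2))
  expect_equal(r$d_artery, sqrt(55^2 + 75^2))
  expect_equal(r$d_nerve, sqrt(1^2 + 8^2))
  expect_equal(r$d_vein, 43.01, tolerance = 1e-4)
  expect_equal(r$d_artery, 93.0, tolerance = 1e-3)
  expect_equal(r$d_nerve, 8.06, tolerance = 1e-3)
  expect_equal(r$d_min, r$d_nerve)
  expect_equal(r$closest, "nerve")
  expect_equal(r$d_min, min(r$d_vein, r$d_artery, r$d_nerve))
})

test_that("only the highest-confidence detection per class is used", {
  far <- bbox(100, 100, 10, 10, "shrapnel", 0.6)
  dets <- rbind(make_dets(), far)
  r <- triage_image(dets)
  # the 0.9 shrapnel at (0,0) is used, not the 0.6 one at (100,100)
  expect_equal(r$d_nerve, sqrt(1 + 64))
  # confidence tie: larger box wins
  tie <- bbox_bind(bbox(0, 0, 10, 10, "shrapnel", 0.9),
                   bbox(40, 40, 30, 30, "shrapnel", 0.9),
                   make_dets()[-1, ])
  r2 <- triage_image(tie)
  expect_equal(unname(r2$d_vein), pair_distance(c(55, 55), c(30, 40)))
})

test_that("triage distances are translation-invariant and scale-covariant", {
  dets <- make_dets()
  r <- triage_image(dets)
  shifted <- dets; shifted$x <- dets$x + 13; shifted$y <- dets$y - 7
  rs <- triage_image(shifted)
  expect_equal(rs[, 2:5], r[, 2:5])
  scaled <- dets
  scaled[, c("x", "y", "w", "h")] <- dets[, c("x", "y", "w", "h")] * 3
  rsc <- triage_image(scaled)
  expect_equal(unlist(rsc[, 2:5]), unlist(r[, 2:5]) * 3)
})

test_that("reference_diameter averages (w + h) / 2 over artery boxes", {
  mk <- function(...) {
    out <- bbox_bind(...)
    out$class <- "artery"
    out
  }
  expect_equal(reference_diameter(mk(bbox(0, 0, 75, 75))), 75)
  expect_equal(reference_diameter(mk(bbox(0, 0, 70, 70), bbox(0, 0, 80, 80))), 75)
  expect_equal(reference_diameter(mk(bbox(0, 0, 60, 80), bbox(0, 0, 80, 100))), 80)
  expect_error(reference_diameter(bbox(0, 0, 10, 10, "vein")), "artery")
})

test_that("gate flags strictly-below-threshold images, monotonically", {
  recs <- data.frame(image_id = 1:4, d_vein = c(40, 70, 100, 130),
                     d_artery = c(35, 65, 95, 125), d_nerve = c(30, 60, 90, 120),
                     d_min = c(30, 60, 90, 120),
                     closest = rep("nerve", 4), stringsAsFactors = FALSE)
  s <- gate(recs, ref = 75, multipliers = c(0.5, 0.75, 1.0, 1.25, 1.5))
  expect_equal(s$flagged$fraction[s$flagged$multiplier == 1.0], 50)
  # monotone nondecreasing in the multiplier
  expect_true(all(diff(s$flagged$fraction) >= 0))
  # boundary equality is NOT flagged (strict comparison)
  s2 <- gate(data.frame(image_id = 1, d_vein = 75, d_artery = 75,
                        d_nerve = 75, d_min = 75, closest = "artery"),
             ref = 75, multipliers = 1)
  expect_equal(s2$flagged$fraction, 0)
  # forced extremes
  zero <- recs; zero$d_min <- 0
  expect_true(all(gate(zero, 75)$flagged$fraction == 100))
  expect_true(all(gate(recs, 1e-6)$flagged$fraction == 0))
  # empty record set
  s3 <- gate(NULL, 75)
  expect_equal(s3$n_images, 0L)
})

test_that("closest-feature frequencies cover all records exactly", {
  set.seed(3)
  n <- 30
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    d <- runif(3, 10, 200)
    cl <- c("vein", "artery", "nerve")[which.min(d)]
    data.frame(image_id = i, d_vein = d[1], d_artery = d[2], d_nerve = d[3],
               d_min = min(d), closest = cl, stringsAsFactors = FALSE)
  }))
  s <- gate(recs, 75)
  expect_equal(sum(s$feature_stats$pct_closest), 100)
  expect_true(all(s$feature_stats$pct_closest <= 100))
  expect_equal(s$mean_d_min, mean(recs$d_min))
  expect_equal(s$n_images, n)
})
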