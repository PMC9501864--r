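base_img <- generate_phantom(phantom_config(image_size = 128), seed = 7,
                             keep_masks = TRUE)

test_that("the identity transform returns the input unchanged", {
  out <- augment_sample(base_img, hflip = FALSE, vflip = FALSE, scale = 1,
                        angle = 0)
  expect_equal(out$pixels, base_img$pixels)
  expect_equal(out$boxes, base_img$boxes)
})

test_that("a horizontal flip applied twice is the identity on boxes", {
  once <- augment_sample(base_img, hflip = TRUE, vflip = FALSE, scale = 1,
                         angle = 0)
  expect_false(isTRUE(all.equal(once$boxes$x, base_img$boxes$x)))
  twice <- augment_sample(once, hflip = TRUE, vflip = FALSE, scale = 1,
                          angle = 0)
  expect_equal(twice$boxes, base_img$boxes)
  expect_equal(twice$pixels, base_img$pixels)
  vtwice <- augment_sample(
    augment_sample(base_img, hflip = FALSE, vflip = TRUE, scale = 1, angle = 0),
    hflip = FALSE, vflip = TRUE, scale = 1, angle = 0)
  expect_equal(vtwice$boxes, base_img$boxes)
})

test_that("pure scaling multiplies box dimensions by the scale factor", {
  out <- augment_sample(base_img, hflip = FALSE, vflip = FALSE, scale = 1.2,
                        angle = 0)
  # boxes away from the border are unclipped: compare their dimensions
  for (i in seq_len(nrow(base_img$boxes))) {
    b0 <- base_img$boxes[i, ]; b1 <- out$boxes[i, ]
    ctr <- 128 / 2
    unclipped <- b1$x > 0 && b1$y > 0 && b1$x + b1$w < 128 && b1$y + b1$h < 128
    if (unclipped) {
      expect_equal(b1$w, b0$w * 1.2)
      expect_equal(b1$h, b0$h * 1.2)
    }
  }
})

test_that("corner-mapped boxes track the transformed feature masks", {
  # flips and pure scaling: mask-derived tight box has IoU >= 0.9 with the
  # corner-mapped box; rotation: the corner-mapped box contains it
  # full-resolution image: the 1 px resampling quantisation is small
  # relative to the feature boxes
  hi <- generate_phantom(phantom_config(), seed = 7, keep_masks = TRUE)
  cases <- list(list(hflip = TRUE, vflip = FALSE, scale = 1, angle = 0),
                list(hflip = FALSE, vflip = TRUE, scale = 1, angle = 0),
                list(hflip = FALSE, vflip = FALSE, scale = 1.15, angle = 0),
                list(hflip = FALSE, vflip = FALSE, scale = 0.85, angle = 0))
  for (par in cases) {
    out <- augment_sample(hi, hflip = par$hflip, vflip = par$vflip,
                          scale = par$scale, angle = par$angle)
    for (i in seq_len(nrow(out$boxes))) {
      mb <- shrapod:::mask_to_box(out$meta$masks[[i]], out$boxes$class[i])
      expect_gte(iou(mb, out$boxes[i, ]), 0.9)
    }
  }
  for (angle in c(30, -75, 145, 261)) {
    out <- augment_sample(base_img, hflip = FALSE, vflip = FALSE, scale = 1,
                          angle = angle)
    for (i in seq_len(nrow(out$boxes))) {
      mb <- shrapod:::mask_to_box(out$meta$masks[[i]], out$boxes$class[i])
      cb <- out$boxes[i, ]
      # containment up to the 1 px discretisation of the resampled mask
      expect_gte(mb$x, cb$x - 1)
      expect_gte(mb$y, cb$y - 1)
      expect_lte(mb$x + mb$w, cb$x + cb$w + 1)
      expect_lte(mb$y + mb$h, cb$y + cb$h + 1)
    }
  }
})

test_that("augmentation preserves per-class box counts (resample rule)", {
  set.seed(31)
  for (i in 1:12) {
    out <- augment_sample(base_img)
    expect_equal(table(out$boxes$class), table(base_img$boxes$class))
  }
})

test_that("forced transforms drop boxes that fully leave the frame", {
  img <- base_img
  img$boxes <- rbind(img$boxes, bbox(0, 0, 4, 4, "shrapnel"))
  img$meta$masks <- NULL
  # zooming in 4x about the centre pushes the corner box far outside
  out <- augment_sample(img, hflip = FALSE, vflip = FALSE, scale = 4,
                        angle = 0)
  expect_lt(nrow(out$boxes), nrow(img$boxes))
  expect_true(all(out$boxes$w > 0 & out$boxes$h > 0))
})

test_that("split_dataset follows the 75/10/15 largest-remainder partition", {
  imgs <- replicate(100, list(pixels = array(0, c(2, 2, 3)),
                              boxes = empty_boxes(), meta = list()),
                    simplify = FALSE)
  s <- split_dataset(imgs, seed = 1)
  expect_equal(lengths(s), c(train = 75, val = 10, test = 15))
  # minimal case: every part non-empty
  s3 <- split_dataset(imgs[1:3], seed = 1)
  expect_equal(unname(lengths(s3)), c(1, 1, 1))
  # deterministic and a true partition
  s2 <- split_dataset(imgs, seed = 1)
  expect_identical(lapply(s, function(p) lapply(p, `[[`, "meta")),
                   lapply(s2, function(p) lapply(p, `[[`, "meta")))
  expect_equal(sum(lengths(s)), 100)
  expect_error(split_dataset(imgs[1:2]), "at least 3")
  expect_error(split_dataset(imgs, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
  # split tags recorded
  expect_true(all(vapply(s$val, function(im) im$meta$split == "val",
                         logical(1))))
})
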