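# Small fixtures for network tests: a handful of box shapes, a reduced-width
# model, and featureless annotated images built in code.

tiny_shapes <- function() {
  bbox_bind(bbox(10, 10, 20, 30), bbox(5, 5, 12, 12, "vein"),
            bbox(40, 40, 25, 18, "artery"), bbox(3, 60, 10, 40, "nerve"),
            bbox(20, 20, 18, 18), bbox(1, 1, 30, 8, "vein"))
}

tiny_model <- function(input_size = 64, width = 0.12, k = 4, seed = 5) {
  anc <- estimate_anchors(tiny_shapes(), k = k, seed = 1)
  build_model(anc, input_size = input_size, n_classes = 4, width = width,
              seed = seed)
}

random_annotated <- function(seed, size = 64) {
  set.seed(seed)
  plane <- matrix(runif(size * size), size, size)
  px <- array(plane, dim = c(size, size, 3))
  boxes <- bbox_bind(bbox(runif(1, 5, size / 2), runif(1, 5, size / 2),
                          runif(1, 8, 20), runif(1, 8, 20),
                          sample(c("shrapnel", "vein", "artery", "nerve"), 1)))
  list(pixels = px, boxes = boxes, meta = list())
}
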