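# Backbone construction, pooled dimensions and fine-tuning behavior.

test_that("pooled feature dimensions are fixed by the architecture", {
  dims <- c(resnet50v2 = 2048L, densenet121 = 1024L, inception_v3 = 2048L,
            inception_resnet = 1536L, vgg19 = 512L)
  # dimension is set by the final block's channels, not the input size, so a
  # small input keeps this check fast
  for (arch in names(dims)) {
    bb <- build_backbone(arch, input_shape = c(64, 64, 3), seed = 1)
    expect_identical(bb$feature_dim, dims[[arch]])
  }
  expect_error(build_backbone("alexnet"), "resnet50v2")
})

test_that("tiny backbone produces the declared feature dimension deterministically", {
  bb <- tiny_backbone(48L, c(32, 32, 3), seed = 2)
  p <- make_test_patch(32, 32, seed = 27) / 255
  f1 <- extract_features(bb, list(p))
  expect_identical(dim(f1), c(1L, 48L))
  expect_identical(f1, extract_features(bb, list(p)))
})

test_that("extract_features stacks rows per patch with batching invariance", {
  bb <- tiny_backbone(16L, c(24, 24, 3), seed = 3)
  ps <- lapply(1:5, function(i) make_test_patch(24, 24, seed = 30 + i) / 255)
  ps[[5]] <- ps[[1]]  # duplicate patch -> duplicate rows
  f_all <- extract_features(bb, ps, batch_size = 5)
  f_one <- extract_features(bb, ps, batch_size = 1)
  expect_identical(dim(f_all), c(5L, 16L))
  expect_equal(f_all, f_one, tolerance = 1e-12)
  expect_equal(f_all[5, ], f_all[1, ])
})

test_that("fine_tune reduces training loss on separable synthetic patches", {
  spec <- synthetic_patch_spec(n = 60, size = 24,
                               proportions = c(0.5, 0.5, 0, 0), seed = 5)
  d <- generate_patches(spec)
  bb <- tiny_backbone(16L, c(24, 24, 3), seed = 4)
  ft <- fine_tune(bb, d$images, d$labels,
                  fine_tune_config(epochs = 5, batch_size = 16,
                                   schedule = lr_schedule(0L, 0.01), seed = 1))
  expect_lt(tail(ft$history$loss, 1), ft$history$loss[1])
  expect_error(fine_tune(bb, d$images, rep(0L, 60)), "two classes")
})

test_that("the L1 penalty shrinks convolution kernels in paired seeded runs", {
  spec <- synthetic_patch_spec(n = 40, size = 24,
                               proportions = c(0.5, 0.5, 0, 0), seed = 6)
  d <- generate_patches(spec)
  bb <- tiny_backbone(8L, c(24, 24, 3), seed = 7)
  run <- function(l1) {
    cfg <- fine_tune_config(epochs = 4, batch_size = 20,
                            schedule = lr_schedule(0L, 0.01), l1 = l1, seed = 2)
    afse:::conv_l1_norm(fine_tune(bb, d$images, d$labels, cfg)$backbone)
  }
  expect_lt(run(5e-3), run(0))
})

test_that("the trunk-frozen policy trains only the head and leaves the trunk intact", {
  # extreme classes (normal vs cancer) so the frozen features carry signal
  spec <- synthetic_patch_spec(n = 60, size = 32,
                               proportions = c(0.5, 0, 0, 0.5), seed = 8)
  d <- generate_patches(spec)
  d$labels <- as.integer(d$labels == 3)
  bb <- tiny_backbone(8L, c(32, 32, 3), seed = 9)
  ft <- fine_tune(bb, d$images, d$labels,
                  fine_tune_config(epochs = 20, frozen = "trunk", dropout = 0,
                                   schedule = lr_schedule(0L, 0.2), seed = 3))
  expect_equal(afse:::conv_l1_norm(ft$backbone), afse:::conv_l1_norm(bb))
  expect_lt(tail(ft$history$loss, 1), ft$history$loss[1])
})

test_that("backbone weights round-trip through save/load", {
  bb <- tiny_backbone(8L, c(16, 16, 3), seed = 10)
  path <- tempfile(fileext = ".rds")
  save_backbone_weights(bb, path)
  bb2 <- tiny_backbone(8L, c(16, 16, 3), seed = 99)  # different init
  bb2 <- load_backbone_weights(bb2, path)
  p <- make_test_patch(16, 16, seed = 33) / 255
  expect_equal(extract_features(bb, list(p)), extract_features(bb2, list(p)),
               ignore_attr = TRUE)
  unlink(path)
})
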