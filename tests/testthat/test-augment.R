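# SAD-gated crop augmentation.

test_that("sad_distance matches its definition and the brute-force loop", {
  expect_equal(sad_distance(matrix(5, 3, 3), matrix(5, 3, 3)), 0)
  expect_equal(sad_distance(matrix(0, 2, 2), matrix(255, 2, 2)), 1020)
  a <- withr::with_seed(1, matrix(runif(25, 0, 255), 5))
  b <- withr::with_seed(2, matrix(runif(25, 0, 255), 5))
  expect_equal(sad_distance(a, b), oracle_sad(a, b))
  expect_equal(sad_distance(a, b), sad_distance(b, a))
  expect_error(sad_distance(a, matrix(0, 4, 5)), "5x5.*4x5")
})

test_that("random_crop honours the gate threshold in both extremes", {
  img <- make_test_patch(40, 40)
  cfg <- augment_config(crop_size = c(16, 16))
  gate_all <- crop_gate(matrix(0, 16, 16), Inf)
  gate_none <- crop_gate(matrix(-1, 16, 16), 0)  # template below any window
  withr::with_seed(3, {
    for (i in 1:5) {
      expect_true(random_crop(img, cfg, gate_all)$accepted)
      expect_false(random_crop(img, cfg, gate_none)$accepted)
    }
  })
  expect_error(random_crop(make_test_patch(8, 8), cfg), "larger than image")
})

test_that("crop offsets are reproducible under a fixed seed", {
  img <- make_test_patch(60, 50, seed = 4)
  cfg <- augment_config(crop_size = c(20, 20))
  o1 <- withr::with_seed(7, replicate(10, random_crop(img, cfg)$offset))
  o2 <- withr::with_seed(7, replicate(10, random_crop(img, cfg)$offset))
  expect_identical(o1, o2)
  expect_true(all(o1 >= 0 & o1 <= 40))
})

test_that("translation moves pixels exactly and (0,0) is the identity", {
  p <- make_test_patch(12, 12)
  expect_equal(random_translate(p, shift = c(0, 0)), p)
  spot <- array(0, dim = c(12, 12, 3))
  spot[4, 5, ] <- 255
  moved <- random_translate(spot, shift = c(1, 2))
  expect_equal(moved[5, 7, ], c(255, 255, 255))
  expect_equal(sum(moved), sum(spot[4, 5, ]))  # reflection adds nothing here
  s1 <- withr::with_seed(5, random_translate(p))
  s2 <- withr::with_seed(5, random_translate(p))
  expect_identical(s1, s2)
})

test_that("rotation: identity at 0, symmetry at 180, permutation at 90", {
  p <- make_test_patch(15, 15)
  expect_equal(random_rotate(p, angle = 0), p)
  # symmetric cross is invariant under 180 degrees
  cross <- array(0, dim = c(11, 11, 3))
  cross[6, , ] <- 200; cross[, 6, ] <- 200
  expect_equal(random_rotate(cross, angle = 180), cross, tolerance = 1e-9)
  # 90-degree turn equals the index permutation out[r, c] = in[n + 1 - c, r]
  n <- 15
  r90 <- random_rotate(p, angle = 90)
  oracle <- p
  for (r in 1:n) for (cc in 1:n) oracle[r, cc, ] <- p[n + 1 - cc, r, ]
  expect_equal(r90, oracle, tolerance = 1e-9)
})

test_that("zoom subsampling selects the strided grid and restores shape", {
  p <- make_test_patch(16, 16)
  expect_equal(random_zoom(p, strides = c(1, 1)), p)
  sub <- random_zoom(p, strides = c(2, 1), resize = FALSE)
  expect_equal(sub, p[seq(1, 16, 2), , , drop = FALSE])
  back <- random_zoom(p, strides = c(2, 2))
  expect_identical(dim(back), dim(p))
  s1 <- withr::with_seed(6, random_zoom(p))
  s2 <- withr::with_seed(6, random_zoom(p))
  expect_identical(s1, s2)
})

test_that("brightness shifts the mean by k and clips at the extremes", {
  p <- make_test_patch(10, 10)
  expect_equal(random_brightness(p, k = 0), p)
  expect_true(all(random_brightness(p, k = 255) == 255))
  interior <- array(100, dim = c(8, 8, 3))
  expect_equal(mean(random_brightness(interior, k = 37)) - mean(interior), 37)
})

test_that("normalization maps 0-255 to 0-1", {
  expect_equal(normalize_patch(array(255, dim = c(2, 2, 3))),
               array(1, dim = c(2, 2, 3)))
  expect_equal(normalize_patch(array(0, dim = c(2, 2, 3))),
               array(0, dim = c(2, 2, 3)))
  expect_equal(normalize_patch(51), 0.2)
})

test_that("augment_dataset emits five patches per accepted crop and logs rejections", {
  imgs <- list(a = make_test_patch(40, 40, seed = 8))
  cfg <- augment_config(crop_size = c(16, 16), crops_per_image = 3)
  out <- augment_dataset(imgs, cfg, gate = NULL, seed = 11)
  expect_equal(length(out$patches), 3 * 5)
  expect_equal(out$log$accepted, 3)
  expect_equal(unique(table(out$manifest$crop)), 5L)
  expect_true(all(vapply(out$patches, function(p) all(p >= 0 & p <= 1), TRUE)))
  expect_true(all(vapply(out$patches, function(p) identical(dim(p), c(16L, 16L, 3L)), TRUE)))
  # all-rejecting gate: zero patches, rejection count equals attempts
  gate <- crop_gate(matrix(-1, 16, 16), 0)
  out0 <- augment_dataset(imgs, cfg, gate, seed = 11)
  expect_equal(length(out0$patches), 0)
  expect_equal(out0$log$rejected, out0$log$attempts)
  expect_error(augment_dataset(list(), cfg), "at least one")
})

test_that("augment_dataset is bit-reproducible for a fixed seed", {
  imgs <- list(make_test_patch(48, 48, seed = 9), make_test_patch(48, 48, seed = 10))
  cfg <- augment_config(crop_size = c(20, 20), crops_per_image = 2)
  r1 <- augment_dataset(imgs, cfg, seed = 21)
  r2 <- augment_dataset(imgs, cfg, seed = 21)
  expect_identical(r1$patches, r2$patches)
  expect_identical(r1$manifest, r2$manifest)
})

test_that("acceptance rate is monotone non-decreasing in the gate threshold", {
  img <- make_test_patch(60, 60, seed = 12)
  cfg <- augment_config(crop_size = c(16, 16), crops_per_image = 25)
  template <- rgb_to_gray(make_test_patch(16, 16, seed = 13))
  rates <- vapply(c(0, 2e4, 1e5, 3e5, Inf), function(th) {
    out <- augment_dataset(list(img), cfg, crop_gate(template, th), seed = 31)
    out$log$accepted / out$log$attempts
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_equal(rates[length(rates)], 1)
})

test_that("crop gate helpers estimate a threshold that accepts the good patches", {
  good <- lapply(1:4, function(i) make_test_patch(16, 16, seed = 40 + i))
  gate <- make_crop_gate(good, margin = 1.01)
  sads <- vapply(good, function(p) sad_distance(rgb_to_gray(p), gate$template), 0)
  expect_true(all(sads < gate$threshold))
})

test_that("patches round-trip through PNG files with 8-bit precision", {
  p <- make_test_patch(24, 20, seed = 50)
  path <- tempfile(fileext = ".png")
  write_patch(p, path)
  q <- read_patch(path)
  expect_identical(dim(q), dim(p))      # orientation preserved
  expect_lt(max(abs(p - q)), 0.51)      # 8-bit quantization only
  unlink(path)
})
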