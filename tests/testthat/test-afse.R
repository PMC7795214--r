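# ANOVA-F scoring, cumulative selection, spectral embedding, serial fusion.

test_that("anova_f matches hand computation and the per-feature loop", {
  # groups A = (0, 1), B = (2, 3): S_A = 4, S_E = 1, F = (4/1)/(1/2) = 8
  X <- matrix(c(0, 1, 2, 3), 4, 1)
  y <- c(0, 0, 1, 1)
  r <- anova_f(X, y)
  expect_equal(r$f, 8, ignore_attr = TRUE)
  expect_equal(r$sa, 4, ignore_attr = TRUE)
  expect_equal(r$se, 1, ignore_attr = TRUE)
  # identical group means -> F = 0
  expect_equal(anova_f(matrix(c(1, 2, 1, 2), 4, 1), y)$f, 0, ignore_attr = TRUE)
  # random matrix, element-wise agreement with the brute-force loop
  pf <- generate_planted_features(n = 60, s = 25, n_informative = 4,
                                  separation = 1.5, seed = 42)
  expect_equal(anova_f(pf$X, pf$y)$f, oracle_anova_f(pf$X, pf$y),
               tolerance = 1e-10)
  expect_error(anova_f(pf$X, rep(1, 60)), "two classes")
})

test_that("anova_f agrees with R's one-way ANOVA and the literal df mode rescales it", {
  pf <- generate_planted_features(n = 40, s = 6, n_informative = 2, seed = 7)
  r <- anova_f(pf$X, pf$y)
  f_ref <- vapply(seq_len(ncol(pf$X)), function(j) {
    summary(stats::aov(pf$X[, j] ~ factor(pf$y)))[[1]]$`F value`[1]
  }, 0)
  expect_equal(r$f, f_ref, tolerance = 1e-8)
  lit <- anova_f(pf$X, pf$y, df = "literal")
  # literal divisors are feature-independent constants: same ranking/weights
  expect_equal(order(-lit$f), order(-r$f))
  expect_equal(lit$fbar, r$fbar, tolerance = 1e-12)
})

test_that("zero within-class variance with class signal is flagged as infinite", {
  X <- cbind(c(0, 0, 1, 1), rnorm(4))
  r <- anova_f(X, c(0, 0, 1, 1))
  expect_true(is.infinite(r$f[1]) && r$flagged[1])
  expect_equal(select_features(r)[1], 1L)  # flagged features rank first
})

test_that("normalize_f produces weights summing to one", {
  expect_equal(normalize_f(c(2, 2)), c(0.5, 0.5))
  expect_equal(normalize_f(c(1, 0, 0)), c(1, 0, 0))
  w <- normalize_f(withr::with_seed(1, runif(20)))
  expect_equal(sum(w), 1)
})

test_that("select_features implements the cumulative stopping rule", {
  expect_equal(select_features(c(1, 0, 0)), 1L)
  expect_equal(sort(select_features(rep(0.25, 4))), 1:4)
  # brute-force scan oracle at threshold 0.5
  fbar <- withr::with_seed(2, { v <- runif(12); v / sum(v) })
  keep <- select_features(fbar, threshold = 0.5)
  ord <- order(-fbar)
  expected <- ord[seq_len(which(cumsum(fbar[ord]) > 0.5)[1])]
  expect_identical(keep, expected)
  expect_error(select_features(numeric(0)), "empty")
})

test_that("selection is invariant to feature permutation (up to the tie rule)", {
  pf <- generate_planted_features(n = 80, s = 30, n_informative = 5,
                                  separation = 2, seed = 11)
  keep <- select_features(anova_f(pf$X, pf$y), threshold = 0.9)
  perm <- withr::with_seed(3, sample.int(30))
  keep_p <- select_features(anova_f(pf$X[, perm], pf$y), threshold = 0.9)
  expect_setequal(perm[keep_p], keep)
})

test_that("spectral embedding separates two clouds and matches the dense eigensolver", {
  set.seed(44)
  X <- rbind(matrix(rnorm(80, 0, 0.5), 40), matrix(rnorm(80, 8, 0.5), 40))
  emb <- suppressWarnings(spectral_embed(X, d = 1, knn = 6))
  s <- sign(emb$coords[, 1])
  expect_true(all(s[1:40] == s[1]) && all(s[41:80] == -s[1]))
  # the coordinates must match a dense eigendecomposition of the entry-wise
  # constructed normalized Laplacian
  A <- afse:::knn_affinity(X, 6)
  orc <- oracle_spectral_coords(A, 1)
  expect_equal(abs_cosine(orc$coords[, 1], emb$coords[, 1]), 1, tolerance = 1e-6)
  expect_equal(emb$values[1], orc$values[1], tolerance = 1e-8)
})

test_that("embedding output width is d and duplicated samples coincide", {
  pf <- generate_planted_features(n = 50, s = 10, seed = 5)
  X <- pf$X
  X[2, ] <- X[1, ]
  for (d in c(1, 3, 5)) {
    emb <- spectral_embed(X, d = d, knn = 5)
    expect_identical(ncol(emb$coords), as.integer(d))
    expect_equal(emb$coords[1, ], emb$coords[2, ], tolerance = 1e-6)
  }
  expect_error(spectral_embed(X, d = 50), "must be <")
})

test_that("a k-component block graph yields k-1 indicator-like coordinates", {
  # three well-separated clusters -> disconnected kNN graph
  set.seed(46)
  X <- rbind(matrix(rnorm(30, 0, 0.2), 15), matrix(rnorm(30, 10, 0.2), 15),
             matrix(rnorm(30, 20, 0.2), 15))
  expect_warning(emb <- spectral_embed(X, d = 2, knn = 4), "3 connected components")
  grp <- rep(1:3, each = 15)
  for (j in 1:2) {
    expect_equal(emb$values[j], 0, tolerance = 1e-9)
    within_var <- tapply(emb$coords[, j], grp, stats::var)
    expect_true(all(within_var < 1e-12))  # piecewise constant on components
  }
})

test_that("Nystrom extension maps new points next to their training cluster", {
  set.seed(47)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30))
  emb <- suppressWarnings(spectral_embed(X, d = 1, knn = 8))
  new <- rbind(rnorm(2, 0), rnorm(2, 8))
  co <- suppressWarnings(predict(emb, new))
  expect_equal(sign(co[1, 1]), sign(mean(emb$coords[1:30, 1])))
  expect_equal(sign(co[2, 1]), sign(mean(emb$coords[31:60, 1])))
})

test_that("serial fusion reproduces the published fused widths", {
  n <- 10
  mats <- lapply(c(200, 200), function(w) matrix(rnorm(n * w), n))
  expect_equal(ncol(serial_fuse(mats)), 400)       # two sources
  mats4 <- lapply(rep(200, 4), function(w) matrix(rnorm(n * w), n))
  expect_equal(ncol(serial_fuse(mats4)), 800)      # all four sources
  one <- matrix(rnorm(20), 5)
  expect_equal(serial_fuse(list(one)), one, ignore_attr = TRUE)
  expect_error(serial_fuse(list(matrix(0, 3, 2), matrix(0, 4, 2))), "row counts")
})

test_that("fusion specs map combination codes to sources and widths", {
  c5 <- fusion_spec("C5")
  expect_identical(c5$sources, c("resnet50v2", "densenet121"))
  expect_equal(c5$fused_width, 400)
  c14 <- fusion_spec("C14")
  expect_equal(c14$fused_width, 800)
  expect_length(fusion_spec("C11")$sources, 3)
  expect_equal(fusion_spec("C13")$fused_width, 600)
  expect_error(fusion_spec("C99"), "unknown combination code")
})

test_that("the pipeline recovers planted features and fuses to the spec width", {
  pf1 <- generate_planted_features(n = 120, s = 40, n_informative = 5,
                                   separation = 4, seed = 21)
  pf2 <- generate_planted_features(n = 120, s = 40, n_informative = 5,
                                   separation = 4, seed = 22)
  pf2$y <- pf1$y  # shared labels, complementary sources
  spec <- fusion_spec("custom", dim_per_source = 8,
                      sources = c("alpha", "beta"))
  fus <- afse_pipeline(list(alpha = pf1$X, beta = pf2$X), pf1$y, spec)
  expect_equal(ncol(fus$fused), 16)
  expect_true(all(pf1$truth$informative %in% fus$report$alpha$kept))
  expect_true(all(pf2$truth$informative %in% fus$report$beta$kept))
  # single-source pipeline equals spectral embedding of that source's selection
  spec1 <- fusion_spec("custom", dim_per_source = 8, sources = "alpha")
  fus1 <- afse_pipeline(list(alpha = pf1$X), pf1$y, spec1)
  keep <- select_features(anova_f(pf1$X, pf1$y))
  emb <- spectral_embed(pf1$X[, keep, drop = FALSE], 8, knn = 10)
  expect_equal(fus1$fused, emb$coords, ignore_attr = TRUE)
})

test_that("transductive and Nystrom modes both embed test rows", {
  pf <- generate_planted_features(n = 90, s = 20, n_informative = 4,
                                  separation = 3, seed = 23)
  tr <- 1:70; te <- 71:90
  spec <- fusion_spec("custom", dim_per_source = 4, sources = "s")
  for (mode in c("nystrom", "transductive")) {
    fus <- afse_pipeline(list(s = pf$X[tr, ]), pf$y[tr], spec,
                         test_sets = list(s = pf$X[te, ]), mode = mode)
    expect_identical(dim(fus$fused_test), c(20L, 4L))
  }
})
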