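# Seeded synthetic data so the full pipeline is testable offline.
#
# The patch generator emulates the structure of a four-class cervical
# histopathology patch dataset: dark elliptical "nuclei" on a lighter
# textured stroma, with nucleus density and size increasing along the
# severity gradient normal -> LSIL -> HSIL -> cancer, the published class
# imbalance (50,370 : 11,914 : 16,677 : 21,059) scaled down, and per-image
# nuisance variation in background brightness and texture (a stand-in for
# staining/illumination variability) that is uncorrelated with class.

#' Synthetic patch dataset specification
#'
#' Per-class nucleus densities/radii are stated for a 96 x 96 patch and are
#' rescaled with patch area so the class geometry is size-invariant. The
#' densities and radii increase strictly with class, giving the severity
#' gradient the classifier is meant to learn.
#'
#' @param n total number of patches.
#' @param size patch side in pixels.
#' @param proportions class mix (normal, LSIL, HSIL, cancer); the default is
#'   the published imbalance profile.
#' @param blob_counts mean nucleus count per class at 96 x 96.
#' @param blob_radii mean nucleus radius (pixels) per class at 96 x 96.
#' @param nucleus_intensity range of nucleus gray values (dark).
#' @param background_range range of mean background gray values (per image).
#' @param texture_amp_range range of background texture amplitude (per image).
#' @param noise_sd_range range of fine pixel-noise standard deviation.
#' @param seed dataset seed; each image draws from a substream derived from
#'   it, so datasets are byte-identical across runs.
#' @return object of class `synthetic_patch_spec`.
#' @export
synthetic_patch_spec <- function(n = 1200L, size = 96L,
                                 proportions = c(50370, 11914, 16677, 21059) / 100020,
                                 blob_counts = c(8, 14, 22, 34),
                                 blob_radii = c(2.6, 3.1, 3.7, 4.4),
                                 nucleus_intensity = c(40, 90),
                                 background_range = c(190, 220),
                                 texture_amp_range = c(4, 18),
                                 noise_sd_range = c(2, 8),
                                 seed = 1L) {
  stopifnot(length(proportions) == length(blob_counts),
            all(diff(blob_counts) > 0), all(diff(blob_radii) > 0))
  structure(list(n = as.integer(n), size = as.integer(size),
                 proportions = proportions / sum(proportions),
                 blob_counts = blob_counts, blob_radii = blob_radii,
                 nucleus_intensity = nucleus_intensity,
                 background_range = background_range,
                 texture_amp_range = texture_amp_range,
                 noise_sd_range = noise_sd_range, seed = as.integer(seed)),
            class = "synthetic_patch_spec")
}

# Draw one ellipse into a gray matrix (darkening only).
draw_ellipse <- function(img, cy, cx, a, b, theta, value) {
  n <- nrow(img); m <- ncol(img)
  r <- max(a, b)
  rr <- max(1L, floor(cy - r)):min(n, ceiling(cy + r))
  cc <- max(1L, floor(cx - r)):min(m, ceiling(cx + r))
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  mask <- u^2 + v^2 <= 1
  sub <- img[rr, cc]
  sub[mask] <- pmin(sub[mask], value)
  img[rr, cc] <- sub
  img
}

synth_patch_image <- function(size, count_mean, radius_mean, spec) {
  # textured background: coarse random field upsampled + fine noise
  base <- stats::runif(1, spec$background_range[1], spec$background_range[2])
  amp <- stats::runif(1, spec$texture_amp_range[1], spec$texture_amp_range[2])
  coarse <- matrix(stats::rnorm(64, 0, amp), 8, 8)
  g <- base + resize_bilinear(coarse, size, size) +
    matrix(stats::rnorm(size * size, 0,
                        stats::runif(1, spec$noise_sd_range[1], spec$noise_sd_range[2])),
           size, size)
  n_blobs <- stats::rpois(1, count_mean)
  for (b in seq_len(n_blobs)) {
    r <- radius_mean * stats::runif(1, 0.7, 1.3)
    g <- draw_ellipse(g,
                      cy = stats::runif(1, 1, size), cx = stats::runif(1, 1, size),
                      a = r * stats::runif(1, 0.8, 1.25), b = r * stats::runif(1, 0.8, 1.25),
                      theta = stats::runif(1, 0, pi),
                      value = stats::runif(1, spec$nucleus_intensity[1],
                                           spec$nucleus_intensity[2]))
  }
  g <- clip_pixels(g)
  # stain-like channel weighting (nuclei read blue-purple, stroma pink)
  out <- array(0, dim = c(size, size, 3))
  out[, , 1] <- clip_pixels(g * 0.95 + 10)
  out[, , 2] <- clip_pixels(g * 0.78)
  out[, , 3] <- clip_pixels(g * 0.98 + 4)
  list(image = out, n_blobs = n_blobs)
}

#' Generate a synthetic four-class patch dataset
#'
#' @param spec a [synthetic_patch_spec()].
#' @return list with `images` (list of `size x size x 3` arrays, 0-255),
#'   `labels` (0-based integers), and `manifest` (per-patch class, nucleus
#'   count and substream seed).
#' @export
generate_patches <- function(spec = synthetic_patch_spec()) {
  k <- length(spec$proportions)
  counts <- floor(spec$n * spec$proportions)
  rem <- spec$n - sum(counts)
  if (rem > 0) {
    top <- order(spec$n * spec$proportions - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  labels <- rep(seq_len(k) - 1L, counts)
  scale_n <- (spec$size / 96)^2
  scale_r <- spec$size / 96
  images <- vector("list", spec$n)
  blobs <- integer(spec$n)
  seeds <- integer(spec$n)
  for (i in seq_len(spec$n)) {
    cls <- labels[i] + 1L
    seeds[i] <- derive_seed(spec$seed, i)
    res <- with_seed(seeds[i], synth_patch_image(
      spec$size,
      count_mean = spec$blob_counts[cls] * scale_n,
      radius_mean = spec$blob_radii[cls] * scale_r, spec))
    images[[i]] <- res$image
    blobs[i] <- res$n_blobs
  }
  list(images = images, labels = labels,
       manifest = data.frame(id = seq_len(spec$n), label = labels,
                             n_nuclei = blobs, seed = seeds))
}

#' Planted-feature matrix specification and generator
#'
#' Generates an `n x s` Gaussian feature matrix in which `n_informative`
#' columns carry class-dependent means (drawn once from
#' `separation * N(0, 1)` per class/column), the remainder are pure noise,
#' and optionally the first `n_redundant` informative columns are duplicated
#' verbatim at the end (for redundancy tests). The informative and redundant
#' column indices are returned for oracle checks.
#'
#' @param n samples.
#' @param s feature columns before redundancy.
#' @param n_informative number of class-informative columns (the first ones).
#' @param separation scale of class-mean differences.
#' @param noise_sd noise standard deviation.
#' @param n_redundant number of informative columns duplicated at the end.
#' @param n_classes number of classes (balanced).
#' @param seed RNG seed.
#' @return list with `X`, `y` (0-based) and `truth` (informative/redundant
#'   indices and the class-mean matrix).
#' @export
generate_planted_features <- function(n = 200L, s = 50L, n_informative = 5L,
                                      separation = 2, noise_sd = 1,
                                      n_redundant = 0L, n_classes = 4L, seed = 1L) {
  stopifnot(n_informative <= s, n_redundant <= n_informative)
  with_seed(seed, {
    y <- rep(seq_len(n_classes) - 1L, length.out = n)
    # class-mean columns are standardized so every informative column has a
    # between-class standard deviation of exactly `separation`
    mu <- matrix(stats::rnorm(n_classes * n_informative), n_classes, n_informative)
    mu <- scale(mu) * separation
    mu[is.nan(mu)] <- 0
    X <- matrix(stats::rnorm(n * s, sd = noise_sd), n, s)
    X[, seq_len(n_informative)] <- X[, seq_len(n_informative)] +
      mu[y + 1L, , drop = FALSE]
    red <- integer(0)
    if (n_redundant > 0) {
      X <- cbind(X, X[, seq_len(n_redundant), drop = FALSE])
      red <- as.integer(s + seq_len(n_redundant))
    }
    list(X = X, y = y,
         truth = list(informative = seq_len(n_informative), redundant = red,
                      class_means = mu))
  })
}
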