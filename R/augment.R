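#' Sum of absolute differences between two grayscale windows
#'
#' The SAD template-matching distance used to reject crops that contain no
#' nuclei: `D = sum over all pixels |S - T|`. It is non-negative, symmetric,
#' and zero exactly when the two windows are identical.
#'
#' @param window,template numeric matrices of identical dimensions.
#' @return a single non-negative number.
#' @export
sad_distance <- function(window, template) {
  if (!is.matrix(window) || !is.matrix(template)) {
    stop("sad_distance() expects grayscale matrices")
  }
  if (!identical(dim(window), dim(template))) {
    stop_shape("sad_distance", dim(window), dim(template))
  }
  sum(abs(window - template))
}

#' Crop gate for SAD-based rejection of empty crops
#'
#' The gate holds a grayscale template `T` and a threshold `D_T`; a crop is
#' accepted when `sad_distance(gray(crop), T) < D_T`. [make_crop_gate()]
#' builds the template as the mean grayscale of user-labelled
#' nucleus-containing example crops, and [estimate_sad_threshold()] estimates
#' `D_T` as the maximum SAD between the template and a set of known-good
#' patches (optionally inflated by `margin`).
#'
#' @param template grayscale matrix with the crop dimensions.
#' @param threshold non-negative SAD acceptance threshold `D_T`.
#' @return an object of class `crop_gate`.
#' @export
crop_gate <- function(template, threshold) {
  stopifnot(is.matrix(template), is.numeric(threshold), threshold >= 0 || is.infinite(threshold))
  structure(list(template = template, threshold = threshold), class = "crop_gate")
}

#' @rdname crop_gate
#' @param good_patches list of example patches (RGB arrays or gray matrices)
#'   that should be accepted.
#' @param margin multiplicative slack applied to the estimated threshold.
#' @export
make_crop_gate <- function(good_patches, margin = 1.05) {
  stopifnot(length(good_patches) > 0)
  grays <- lapply(good_patches, rgb_to_gray)
  template <- Reduce(`+`, grays) / length(grays)
  crop_gate(template, estimate_sad_threshold(template, good_patches) * margin)
}

#' @rdname crop_gate
#' @export
estimate_sad_threshold <- function(template, good_patches) {
  max(vapply(good_patches, function(p) sad_distance(rgb_to_gray(p), template), 0))
}

#' Augmentation configuration
#'
#' Bundles the tunables of the crop-and-augment procedure: crop size,
#' translation bound, rotation, zoom stride range and brightness range.
#' The literal translation range (the full patch side) would move content
#' entirely out of frame, so offsets are bounded by `max_translate_frac`
#' of the patch side; zoom strides similarly default to `{1, 2}`.
#'
#' @param crop_size integer `(d1, d2)` crop height and width in pixels.
#' @param crops_per_image number of crop attempts per source image; the
#'   default (`NULL`) uses the tiling count `floor(H/d1) * floor(W/d2)`.
#' @param max_translate_frac upper bound on |shift| as a fraction of side.
#' @param zoom_strides integer vector of admissible subsampling strides.
#' @param brightness_range half-width of the additive brightness offset; the
#'   offset is the difference of two uniform draws on `[0, brightness_range]`.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(crop_size = c(200, 200), crops_per_image = NULL,
                           max_translate_frac = 0.2, zoom_strides = c(1L, 2L),
                           brightness_range = 255) {
  stopifnot(length(crop_size) == 2, all(crop_size > 0),
            max_translate_frac >= 0, all(zoom_strides >= 1))
  structure(list(crop_size = as.integer(crop_size),
                 crops_per_image = crops_per_image,
                 max_translate_frac = max_translate_frac,
                 zoom_strides = as.integer(zoom_strides),
                 brightness_range = brightness_range),
            class = "augment_config")
}

#' Random crop with SAD gating
#'
#' Draws a crop window uniformly inside the image (offsets clamped so the
#' window always fits) and accepts it when its grayscale SAD distance to the
#' gate template is below the gate threshold. Rejection is a countable
#' outcome, not an error.
#'
#' @param img `H x W x 3` source image array, pixels in `[0, 255]`.
#' @param cfg an [augment_config()].
#' @param gate a [crop_gate()], or `NULL` to accept everything.
#' @return list with `patch` (the crop, or `NULL` when rejected), `accepted`,
#'   `offset` (0-based row/col) and `sad` (distance to the template).
#' @export
random_crop <- function(img, cfg = augment_config(), gate = NULL) {
  d <- cfg$crop_size
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < d[1] || w < d[2]) {
    stop(sprintf("crop %dx%d larger than image %dx%d", d[1], d[2], h, w))
  }
  p <- sample.int(h - d[1] + 1L, 1L) - 1L
  q <- sample.int(w - d[2] + 1L, 1L) - 1L
  patch <- img[p + seq_len(d[1]), q + seq_len(d[2]), , drop = FALSE]
  sad <- NA_real_
  accepted <- TRUE
  if (!is.null(gate)) {
    sad <- sad_distance(rgb_to_gray(patch), gate$template)
    accepted <- sad < gate$threshold
  }
  list(patch = if (accepted) patch else NULL, accepted = accepted,
       offset = c(p, q), sad = sad)
}

#' Random integer translation with reflected borders
#'
#' Shifts the patch by integer offsets `(t_x, t_y)` drawn uniformly from
#' `[0, max_translate_frac * side]`; vacated pixels are filled by reflection
#' so tissue statistics are preserved.
#'
#' @param patch `H x W x 3` array.
#' @param cfg an [augment_config()].
#' @param shift optional fixed `(t_x, t_y)` overriding the random draw.
#' @return translated patch, same shape.
#' @export
random_translate <- function(patch, cfg = augment_config(), shift = NULL) {
  h <- dim(patch)[1]; w <- dim(patch)[2]
  if (is.null(shift)) {
    shift <- c(sample.int(max(1L, floor(cfg$max_translate_frac * h)) + 1L, 1L),
               sample.int(max(1L, floor(cfg$max_translate_frac * w)) + 1L, 1L)) - 1L
  }
  ri <- reflect_index(seq_len(h) - shift[1], h)
  ci <- reflect_index(seq_len(w) - shift[2], w)
  patch[ri, ci, , drop = FALSE]
}

#' Random rotation about the patch center
#'
#' Rotates by an angle drawn uniformly from `[0, 360)` degrees using inverse
#' mapping with bilinear interpolation; out-of-frame samples are reflected.
#' Angles that are exact multiples of 90 degrees reproduce the corresponding
#' index permutation exactly.
#'
#' @param patch `H x W x 3` array.
#' @param angle optional fixed angle in degrees overriding the random draw.
#' @return rotated patch, same shape.
#' @export
random_rotate <- function(patch, angle = NULL) {
  if (is.null(angle)) angle <- stats::runif(1, 0, 360)
  if (angle %% 360 == 0) return(patch)
  h <- dim(patch)[1]; w <- dim(patch)[2]
  a <- angle * pi / 180
  c0r <- (h + 1) / 2; c0c <- (w + 1) / 2
  dr <- matrix(seq_len(h) - c0r, h, w)
  dc <- matrix(seq_len(w) - c0c, h, w, byrow = TRUE)
  sr <- c0r + cos(a) * dr - sin(a) * dc
  sc <- c0c + sin(a) * dr + cos(a) * dc
  # snap to grid when the rotation lands on integer coordinates
  sr[abs(sr - round(sr)) < 1e-9] <- round(sr[abs(sr - round(sr)) < 1e-9])
  sc[abs(sc - round(sc)) < 1e-9] <- round(sc[abs(sc - round(sc)) < 1e-9])
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ri0 <- as.vector(reflect_index(r0, h)); ri1 <- as.vector(reflect_index(r0 + 1, h))
  ci0 <- as.vector(reflect_index(c0, w)); ci1 <- as.vector(reflect_index(c0 + 1, w))
  i00 <- cbind(ri0, ci0); i10 <- cbind(ri1, ci0)
  i01 <- cbind(ri0, ci1); i11 <- cbind(ri1, ci1)
  out <- array(0, dim = dim(patch))
  for (ch in seq_len(dim(patch)[3])) {
    p <- patch[, , ch]
    out[, , ch] <- (1 - fr) * (1 - fc) * p[i00] + fr * (1 - fc) * p[i10] +
      (1 - fr) * fc * p[i01] + fr * fc * p[i11]
  }
  out
}

#' Random zoom by strided subsampling
#'
#' Subsamples rows with stride `m` and columns with stride `n` (drawn from
#' `cfg$zoom_strides`), then restores the patch to its original size with
#' bilinear interpolation so downstream descriptors keep a fixed dimension.
#'
#' @inheritParams random_translate
#' @param strides optional fixed `(m, n)` overriding the random draw.
#' @param resize if `FALSE`, return the raw subsampled patch.
#' @return zoomed patch (same shape unless `resize = FALSE`).
#' @export
random_zoom <- function(patch, cfg = augment_config(), strides = NULL, resize = TRUE) {
  if (is.null(strides)) {
    strides <- c(sample(cfg$zoom_strides, 1L), sample(cfg$zoom_strides, 1L))
  }
  h <- dim(patch)[1]; w <- dim(patch)[2]
  sub <- patch[seq(1L, h, by = strides[1]), seq(1L, w, by = strides[2]), , drop = FALSE]
  if (!resize || identical(dim(sub), dim(patch))) return(sub)
  resize_bilinear(sub, h, w)
}

#' Random additive brightness shift
#'
#' Adds a scalar `k = -rand(b) + rand(b)` (difference of two uniform draws on
#' `[0, brightness_range]`) to every channel and clips to `[0, 255]`.
#'
#' @inheritParams random_translate
#' @param k optional fixed offset overriding the random draw.
#' @return brightness-shifted patch.
#' @export
random_brightness <- function(patch, cfg = augment_config(), k = NULL) {
  if (is.null(k)) {
    k <- -stats::runif(1, 0, cfg$brightness_range) + stats::runif(1, 0, cfg$brightness_range)
  }
  clip_pixels(patch + k)
}

#' Normalize pixel values to `[0, 1]`
#'
#' Divides every value by 255 so low-intensity structure is not swamped by
#' high-value regions during training.
#'
#' @param patch numeric array or matrix on the 0-255 scale.
#' @return the patch divided by 255.
#' @export
normalize_patch <- function(patch) patch / 255

#' Crop-and-augment a set of source images
#'
#' For each source image, draws `crops_per_image` SAD-gated random crops;
#' every accepted crop contributes five output patches (the crop itself plus
#' one translated, one rotated, one zoomed and one brightness-adjusted
#' variant), all normalized to `[0, 1]`. Rejected crops are counted, not
#' errors. Each image uses an independent RNG substream derived from `seed`
#' and the image counter, so runs are reproducible and order-independent.
#'
#' @param images list of `H x W x 3` arrays (pixels 0-255), optionally named.
#' @param cfg an [augment_config()].
#' @param gate a [crop_gate()] or `NULL`.
#' @param seed integer run seed.
#' @param normalize divide outputs by 255 (default `TRUE`).
#' @return list with `patches` (list of arrays), `manifest` (data frame with
#'   source id, crop offsets, transform tag and substream seed) and `log`
#'   (per-image accepted/rejected counts).
#' @export
augment_dataset <- function(images, cfg = augment_config(), gate = NULL,
                            seed = 1L, normalize = TRUE) {
  if (length(images) == 0) stop("augment_dataset() needs at least one source image")
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(images))
  patches <- list()
  rows <- list()
  log <- data.frame(source = ids, attempts = 0L, accepted = 0L, rejected = 0L)
  transforms <- c("crop", "translate", "rotate", "zoom", "brightness")
  for (i in seq_along(images)) {
    img <- images[[i]]
    n_try <- cfg$crops_per_image
    if (is.null(n_try)) {
      n_try <- max(1L, (dim(img)[1] %/% cfg$crop_size[1]) *
                     (dim(img)[2] %/% cfg$crop_size[2]))
    }
    sub_seed <- derive_seed(seed, i)
    res <- with_seed(sub_seed, {
      out <- list()
      acc <- 0L
      for (j in seq_len(n_try)) {
        cr <- random_crop(img, cfg, gate)
        if (!cr$accepted) next
        acc <- acc + 1L
        variants <- list(
          cr$patch,
          random_translate(cr$patch, cfg),
          random_rotate(cr$patch),
          random_zoom(cr$patch, cfg),
          random_brightness(cr$patch, cfg)
        )
        for (v in seq_along(variants)) {
          p <- variants[[v]]
          if (normalize) p <- normalize_patch(p)
          out[[length(out) + 1L]] <- list(
            patch = p,
            row = data.frame(source = ids[i], crop = acc,
                             offset_row = cr$offset[1], offset_col = cr$offset[2],
                             transform = transforms[v], seed = sub_seed))
        }
      }
      list(out = out, accepted = acc, attempts = n_try)
    })
    log$attempts[i] <- res$attempts
    log$accepted[i] <- res$accepted
    log$rejected[i] <- res$attempts - res$accepted
    for (o in res$out) {
      patches[[length(patches) + 1L]] <- o$patch
      rows[[length(rows) + 1L]] <- o$row
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), crop = integer(), offset_row = integer(),
               offset_col = integer(), transform = character(), seed = integer())
  list(patches = patches, manifest = manifest, log = log)
}
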