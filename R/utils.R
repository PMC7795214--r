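# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a per-item substream seed from a run seed and a counter, kept below
# .Machine$integer.max so it is always a valid set.seed() input.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 48271 + as.double(counter) * 16807) %% 2147483647)
}

# Mirror indices into [1, n] (reflect border policy, edge not repeated).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- ((i - 1L) %% p + p) %% p
  ifelse(j >= n, p - j, j) + 1L
}

clip_pixels <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

is_patch <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

stop_shape <- function(what, a, b) {
  stop(sprintf(
    "%s: dimensions differ (%s vs %s)", what,
    paste(a, collapse = "x"), paste(b, collapse = "x")
  ), call. = FALSE)
}

#' Convert an RGB patch to grayscale
#'
#' Uses ITU-R BT.601 luma weights (0.299, 0.587, 0.114). A matrix input is
#' returned unchanged so grayscale patches pass through transparently.
#'
#' @param img an `H x W x 3` numeric array or an `H x W` matrix.
#' @return an `H x W` numeric matrix on the same intensity scale as the input.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (!is_patch(img)) stop("expected an H x W x 3 array or an H x W matrix")
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Bilinear image resize
#'
#' Center-aligned bilinear interpolation, used to restore zoomed patches to
#' the working patch size and to bring patches to the HOG working resolution.
#'
#' @param img matrix or `H x W x C` array.
#' @param height,width output size in pixels.
#' @return resized matrix or array with `C` preserved.
#' @export
resize_bilinear <- function(img, height, width) {
  single <- is.matrix(img)
  if (single) img <- array(img, dim = c(dim(img), 1L))
  h <- dim(img)[1]; w <- dim(img)[2]; nc <- dim(img)[3]
  ri <- (seq_len(height) - 0.5) * h / height + 0.5
  ci <- (seq_len(width) - 0.5) * w / width + 0.5
  ri <- pmin(pmax(ri, 1), h); ci <- pmin(pmax(ci, 1), w)
  r0 <- pmin(floor(ri), h - 1L); c0 <- pmin(floor(ci), w - 1L)
  if (h == 1L) r0 <- rep(1, height)
  if (w == 1L) c0 <- rep(1, width)
  fr <- ri - r0; fc <- ci - c0
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  out <- array(0, dim = c(height, width, nc))
  FR <- matrix(fr, height, width); FC <- matrix(fc, height, width, byrow = TRUE)
  for (ch in seq_len(nc)) {
    p <- img[, , ch]
    out[, , ch] <- (1 - FR) * (1 - FC) * p[cbind(rep(r0, width), rep(c0, each = height))] +
      FR * (1 - FC) * p[cbind(rep(r1, width), rep(c0, each = height))] +
      (1 - FR) * FC * p[cbind(rep(r0, width), rep(c1, each = height))] +
      FR * FC * p[cbind(rep(r1, width), rep(c1, each = height))]
  }
  if (single && nc == 1L) out[, , 1] else out
}

#' Read an image file as a pixel patch
#'
#' Thin wrapper over `EBImage::readImage()` returning pixels on the 0-255
#' scale in row/column (H x W x channel) orientation.
#'
#' @param path PNG/TIFF/JPEG file path.
#' @return `H x W x 3` array (grayscale files are replicated across channels).
#' @export
read_patch <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("read_patch() requires the EBImage package")
  }
  img <- EBImage::readImage(path)
  px <- EBImage::imageData(img)
  # EBImage stores x (column) first; transpose to row-major H x W.
  if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
  px <- aperm(px[, , seq_len(min(3L, dim(px)[3])), drop = FALSE], c(2, 1, 3))
  if (dim(px)[3] == 1L) px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
  px * 255
}

#' Write a pixel patch to an image file
#'
#' @param patch `H x W x 3` array on the 0-255 (or 0-1) scale.
#' @param path output file; the extension selects the format.
#' @export
write_patch <- function(patch, path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("write_patch() requires the EBImage package")
  }
  if (max(patch) > 1) patch <- patch / 255
  img <- EBImage::Image(aperm(clip_pixels(patch, 0, 1), c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(img, path)
  invisible(path)
}
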