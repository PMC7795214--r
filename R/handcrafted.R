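#' Local binary pattern codes
#'
#' Per-pixel LBP code `sum_i p(g_i - g_o) * 2^i` over `neighbors` circular
#' neighbors at radius `radius`, where the sign function maps ties and
#' negative differences to 1 (`p(x) = 1` when `x <= 0`). With the default
#' `radius = 1, neighbors = 8` the neighborhood is the 8-connected integer
#' ring (traversed clockwise from the top-left corner) and codes lie in
#' `[0, 255]`; for `radius >= 2` neighbor grays are sampled on the circle
#' with bilinear interpolation. Border pixels without a full neighborhood
#' are excluded, so the code grid shrinks by `radius` on each side.
#'
#' @param gray `H x W` numeric matrix.
#' @param radius circular neighborhood radius (pixels).
#' @param neighbors number of sampling points on the circle.
#' @return integer-valued code matrix of size `(H - 2r) x (W - 2r)`.
#' @export
lbp_codes <- function(gray, radius = 1L, neighbors = 8L) {
  if (!is.matrix(gray)) stop("lbp_codes() expects a grayscale matrix, not an array")
  h <- nrow(gray); w <- ncol(gray)
  r <- as.integer(radius)
  if (h <= 2 * r || w <= 2 * r) stop("patch too small for the requested LBP radius")
  ih <- h - 2L * r; iw <- w - 2L * r
  center <- gray[r + seq_len(ih), r + seq_len(iw), drop = FALSE]
  codes <- matrix(0, ih, iw)
  if (r == 1L && neighbors == 8L) {
    # clockwise from the top-left corner of the 8-neighborhood
    off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
    for (i in seq_along(off)) {
      nb <- gray[r + off[[i]][1] + seq_len(ih), r + off[[i]][2] + seq_len(iw), drop = FALSE]
      codes <- codes + (nb <= center) * 2^(i - 1)
    }
    return(codes)
  }
  ang <- -2 * pi * (seq_len(neighbors) - 1) / neighbors + pi / 2  # clockwise from top
  for (i in seq_len(neighbors)) {
    dr <- -r * sin(ang[i]); dc <- r * cos(ang[i])
    rr <- (r + seq_len(ih)) + dr
    cc <- (r + seq_len(iw)) + dc
    r0 <- floor(rr); c0 <- floor(cc)
    fr <- rr - r0; fc <- cc - c0
    nb <- (1 - fr) %o% (1 - fc) * gray[cbind(rep(r0, iw), rep(c0, each = ih))] +
      fr %o% (1 - fc) * gray[cbind(rep(r0 + 1, iw), rep(c0, each = ih))] +
      (1 - fr) %o% fc * gray[cbind(rep(r0, iw), rep(c0 + 1, each = ih))] +
      fr %o% fc * gray[cbind(rep(r0 + 1, iw), rep(c0 + 1, each = ih))]
    codes <- codes + (nb <= center + 1e-12) * 2^(i - 1)
  }
  codes
}

#' LBP code histogram
#'
#' Relative frequency of each code value: `H_f(k) = n_k / n` over
#' `k = 0, ..., levels - 1`. The result is a probability vector.
#'
#' @param codes code matrix from [lbp_codes()].
#' @param levels number of code values (256 for 8 neighbors).
#' @return numeric vector of length `levels` summing to 1.
#' @export
lbp_histogram <- function(codes, levels = 256L) {
  counts <- tabulate(as.integer(codes) + 1L, nbins = levels)
  counts / length(codes)
}

#' Histogram-of-oriented-gradients descriptor
#'
#' The patch is resized to `work_size` pixels square, gradients are taken by
#' central differences with replicated edges, and unsigned gradient
#' orientations on `[0, 180)` degrees are accumulated (magnitude-weighted,
#' hard assignment) into `bins` orientation bins per `cell x cell` pixel
#' cell. Each cell histogram is L2-normalized independently (no overlapping
#' blocks). The default configuration, 120 x 120 working size with 10 x 10
#' cells and 8 bins, yields a 12 * 12 * 8 = 1152-dimensional descriptor.
#'
#' @param gray `H x W` numeric matrix.
#' @param cell cell side in pixels.
#' @param bins orientation bin count on `[0, 180)`.
#' @param work_size working image side; must be a multiple of `cell`.
#' @return numeric vector of length `(work_size/cell)^2 * bins`.
#' @export
hog_descriptor <- function(gray, cell = 10L, bins = 8L, work_size = 120L) {
  if (!is.matrix(gray)) stop("hog_descriptor() expects a grayscale matrix")
  if (nrow(gray) < cell || ncol(gray) < cell) {
    stop("patch smaller than one HOG cell")
  }
  if (work_size %% cell != 0) stop("work_size must be a multiple of cell")
  g <- if (nrow(gray) == work_size && ncol(gray) == work_size) gray else
    resize_bilinear(gray, work_size, work_size)
  n <- work_size
  gx <- g[, c(2:n, n)] - g[, c(1, 1:(n - 1))]   # column direction
  gy <- g[c(2:n, n), ] - g[c(1, 1:(n - 1)), ]   # row direction
  mag <- sqrt(gx^2 + gy^2)
  mag[mag < 1e-9] <- 0        # resampling noise must not register as texture
  ang <- (atan2(gy, gx) * 180 / pi) %% 180
  bin <- pmin(floor(ang / (180 / bins)), bins - 1)
  ncell <- n %/% cell
  cell_r <- (seq_len(n) - 1L) %/% cell
  cell_id <- cell_r[row(g)] + ncell * cell_r[col(g)]          # 0-based cell index
  idx <- cell_id * bins + bin + 1                              # histogram slot
  desc <- numeric(ncell * ncell * bins)
  acc <- rowsum(as.vector(mag), group = as.vector(idx))
  desc[as.integer(rownames(acc))] <- acc
  dim(desc) <- c(bins, ncell * ncell)
  nrm <- sqrt(colSums(desc^2))
  nz <- nrm > 0
  desc[, nz] <- sweep(desc[, nz, drop = FALSE], 2, nrm[nz], `/`)
  as.vector(desc)
}

#' Traditional image feature (TIF) vector
#'
#' Serial concatenation of the LBP histogram and the HOG descriptor of a
#' patch: `[LBP || HOG]`, 256 + 1152 = 1408 values under defaults.
#'
#' @param patch `H x W x 3` array or grayscale matrix.
#' @param lbp_radius,lbp_neighbors LBP parameters (see [lbp_codes()]).
#' @param hog_cell,hog_bins,hog_work_size HOG parameters (see
#'   [hog_descriptor()]).
#' @return numeric vector; the LBP histogram occupies the first entries.
#' @export
tif_vector <- function(patch, lbp_radius = 1L, lbp_neighbors = 8L,
                       hog_cell = 10L, hog_bins = 8L, hog_work_size = 120L) {
  gray <- rgb_to_gray(patch)
  c(lbp_histogram(lbp_codes(gray, lbp_radius, lbp_neighbors),
                  levels = 2L^lbp_neighbors),
    hog_descriptor(gray, hog_cell, hog_bins, hog_work_size))
}

#' TIF feature matrix for a list of patches
#'
#' @param patches list of patches (arrays or grayscale matrices).
#' @param ... passed to [tif_vector()].
#' @return `n x s` matrix, one TIF row per patch, with a `"source"`
#'   attribute tagging provenance.
#' @export
tif_features <- function(patches, ...) {
  X <- t(vapply(patches, tif_vector, tif_vector(patches[[1]], ...), ...))
  attr(X, "source") <- "TIF"
  X
}
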