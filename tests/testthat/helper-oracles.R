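# Independent brute-force oracles used to cross-check the implementation.

# SAD by explicit double loop.
oracle_sad <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    s <- s + abs(a[i, j] - b[i, j])
  }
  s
}

# LBP codes by per-pixel neighbor loop (radius 1, 8 neighbors, clockwise
# from the top-left corner, tie -> 1).
oracle_lbp <- function(gray) {
  h <- nrow(gray); w <- ncol(gray)
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0, h - 2, w - 2)
  for (r in 2:(h - 1)) for (cc in 2:(w - 1)) {
    code <- 0
    for (i in seq_along(off)) {
      gi <- gray[r + off[[i]][1], cc + off[[i]][2]]
      if (gi - gray[r, cc] <= 0) code <- code + 2^(i - 1)
    }
    out[r - 1, cc - 1] <- code
  }
  out
}

# One-way ANOVA F per feature via direct textbook sums.
oracle_anova_f <- function(X, y) {
  groups <- unique(y)
  k <- length(groups)
  n <- nrow(X)
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    gm <- mean(x)
    sa <- 0; se <- 0
    for (g in groups) {
      xg <- x[y == g]
      sa <- sa + length(xg) * (mean(xg) - gm)^2
      se <- se + sum((xg - mean(xg))^2)
    }
    (sa / (k - 1)) / (se / (n - k))
  }, 0)
}

# Mann-Whitney AUC of scores against binary labels (no ties assumed).
oracle_auc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Chi-square score per the observed/expected class-sum construction.
oracle_chi2 <- function(X, y) {
  cls <- sort(unique(y))
  vapply(seq_len(ncol(X)), function(j) {
    tot <- sum(X[, j])
    s <- 0
    for (g in cls) {
      A <- sum(X[y == g, j])
      T <- mean(y == g) * tot
      if (T > 0) s <- s + (A - T)^2 / T
    }
    s
  }, 0)
}

# Normalized graph Laplacian built entry by entry (dense oracle).
oracle_normalized_laplacian <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    di <- if (deg[i] > 0) 1 / sqrt(deg[i]) else 0
    dj <- if (deg[j] > 0) 1 / sqrt(deg[j]) else 0
    L[i, j] <- (if (i == j) 1 else 0) - di * A[i, j] * dj
  }
  L
}

# A small RGB test patch with reproducible content.
make_test_patch <- function(h = 24, w = 24, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

# Dense-eigendecomposition oracle for the spectral embedding: builds the
# normalized Laplacian entry by entry, shifts the trivial direction up,
# takes the d smallest eigenvectors and applies the D^(-1/2) row scaling.
oracle_spectral_coords <- function(A, d) {
  L <- oracle_normalized_laplacian(A)
  n <- nrow(A)
  deg <- rowSums(A)
  v0 <- sqrt(deg)
  v0 <- v0 / sqrt(sum(v0^2))
  eg <- eigen(L + 2 * v0 %*% t(v0), symmetric = TRUE)
  vals <- rev(eg$values)
  vecs <- eg$vectors[, n:1, drop = FALSE]
  list(coords = vecs[, seq_len(d), drop = FALSE] *
         ifelse(deg > 0, 1 / sqrt(deg), 0),
       values = vals[seq_len(d)])
}

# Cosine similarity between two coordinate vectors (1 = same direction up
# to sign).
abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
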