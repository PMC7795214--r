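# ANOVA F-value scoring, cumulative-weight feature selection, spectral
# embedding and serial fusion — the core of the fusion pipeline.

#' Per-feature one-way ANOVA F statistics
#'
#' For every feature (column) computes the between-class sum of squares
#' `S_A = sum_i n_i (mean_i - grand_mean)^2`, the pooled within-class sum of
#' squares `S_E`, and the statistic `F = (S_A / df1) / (S_E / df2)`. With
#' `df = "standard"` the usual one-way ANOVA degrees of freedom are used
#' (`df1 = k - 1`, `df2 = n - k` for `k` classes); `df = "literal"` divides
#' by the feature length minus one and `n - 1` instead. The two modes differ
#' only by a constant factor shared by all features, so the induced ranking
#' and the normalized weights are identical.
#'
#' Features with zero within-class variance but positive between-class
#' variance get an infinite statistic and are flagged; they sort first and
#' are excluded from the weight normalization.
#'
#' @param X `n x s` numeric feature matrix.
#' @param y class labels, one per row (at least two classes).
#' @param df degrees-of-freedom convention, `"standard"` or `"literal"`.
#' @return object of class `afse_anova` with elements `sa`, `se`, `f`,
#'   `fbar` (normalized weights summing to 1), `df1`, `df2` and `flagged`.
#' @export
anova_f <- function(X, y, df = c("standard", "literal")) {
  df <- match.arg(df)
  X <- as.matrix(X)
  y <- as.integer(factor(y))
  n <- nrow(X)
  if (n != length(y)) stop("length(y) must equal nrow(X)")
  k <- length(unique(y))
  if (k < 2L) stop("anova_f() requires at least two classes")
  counts <- tabulate(y, nbins = k)
  gm <- colMeans(X)
  means <- rowsum(X, y) / counts
  sa <- colSums(counts * sweep(means, 2, gm)^2)
  se <- colSums((X - means[y, , drop = FALSE])^2)
  if (df == "standard") {
    df1 <- k - 1L; df2 <- n - k
  } else {
    df1 <- ncol(X) - 1L; df2 <- n - 1L
  }
  f <- (sa / df1) / (se / df2)
  f[sa == 0 & se == 0] <- 0          # constant features carry no signal
  flagged <- is.infinite(f)
  fin <- f
  fin[flagged] <- 0
  tot <- sum(fin)
  fbar <- if (tot > 0) fin / tot else rep(0, length(f))
  structure(list(sa = sa, se = se, f = f, fbar = fbar,
                 df1 = df1, df2 = df2, flagged = flagged, n = n, k = k),
            class = "afse_anova")
}

#' Normalize scores to weights summing to one
#'
#' `x_bar_i = x_i / sum(x)`; shared by the ANOVA-F weights and the feature
#' diagnostics.
#'
#' @param f non-negative score vector.
#' @return vector summing to 1 (all zeros if the input sums to 0).
#' @export
normalize_f <- function(f) {
  tot <- sum(f)
  if (tot <= 0) return(rep(0, length(f)))
  f / tot
}

#' Cumulative-weight feature selection
#'
#' Sorts features by normalized F weight in descending order (ties broken by
#' original index) and retains features up to and including the first at
#' which the running weight sum exceeds `threshold` (99.9% by default).
#' Features flagged as infinite-F are ranked ahead of all others. If the
#' running sum never exceeds the threshold, all features are kept.
#'
#' @param result an `afse_anova` object (or a bare weight vector).
#' @param threshold cumulative normalized-weight stopping threshold.
#' @return integer vector of original column indices, in retained order.
#' @export
select_features <- function(result, threshold = 0.999) {
  fbar <- if (inherits(result, "afse_anova")) result$fbar else normalize_f(result)
  flagged <- if (inherits(result, "afse_anova")) result$flagged else
    rep(FALSE, length(fbar))
  if (length(fbar) == 0) stop("select_features(): empty feature set")
  key <- fbar + ifelse(flagged, Inf, 0)
  ord <- order(-key)                     # radix sort: stable, ties by index
  cum <- cumsum(fbar[ord])
  stop_at <- which(cum > threshold)
  keep <- if (length(stop_at)) min(stop_at) else length(ord)
  ord[seq_len(keep)]
}

# Binary k-nearest-neighbour affinity matrix, symmetrized by max. Distance
# ties at the k-th neighbour are all included, so duplicated samples receive
# identical graph rows.
knn_affinity <- function(X, knn) {
  n <- nrow(X)
  dm <- as.matrix(stats::dist(X))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- dm[i, -i]
    th <- sort(d, partial = knn)[knn]
    A[i, dm[i, ] <= th + 1e-12] <- 1
    A[i, i] <- 0
  }
  pmax(A, t(A))
}

#' Laplacian-eigenmap spectral embedding
#'
#' Builds a symmetrized k-nearest-neighbour binary affinity graph over the
#' rows of `X`, forms the normalized Laplacian
#' `L = D^(-1/2) (D - A) D^(-1/2)`, and takes the eigenvectors of the `d`
#' smallest non-trivial eigenvalues as coordinates. The fitted model retains
#' the training eigenbasis so new samples can be mapped by a Nystrom
#' extension (see [predict.spectral_embedding()]).
#'
#' @param X `n x s` feature matrix (rows are samples).
#' @param d target embedding dimension (`d < n`).
#' @param knn number of nearest neighbours for the affinity graph.
#' @return object of class `spectral_embedding` with `coords` (`n x d`),
#'   `values` (the retained eigenvalues) and the fitted basis.
#' @export
spectral_embed <- function(X, d, knn = 10L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (d >= n) stop(sprintf("embedding dimension d = %d must be < n = %d", d, n))
  knn <- min(knn, n - 1L)
  A <- knn_affinity(X, knn)
  deg <- rowSums(A)
  if (any(deg == 0)) warning("isolated samples in the affinity graph")
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  L <- diag(n) - t(A * dinv) * dinv      # D^-1/2 A D^-1/2 subtracted from I
  L <- (L + t(L)) / 2
  # Deflate the trivial eigenvector (D^(1/2) 1) so the d smallest remaining
  # eigenvectors are the non-trivial coordinates even when the graph is
  # disconnected (each extra component then contributes an indicator
  # coordinate instead of hiding in a degenerate null space).
  v0 <- sqrt(pmax(deg, 0))
  v0 <- v0 / sqrt(sum(v0^2))
  eg <- eigen(L + 2 * tcrossprod(v0), symmetric = TRUE)
  vals <- rev(eg$values)                 # ascending
  vecs <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
  n_comp <- 1L + sum(vals < 1e-9)
  if (n_comp > 1L) {
    warning(sprintf(
      "affinity graph has %d connected components; component-indicator coordinates retained", n_comp))
  }
  keep <- seq_len(d)
  # Laplacian-eigenmaps coordinates: rescale rows by D^(-1/2) so the
  # coordinates solve the random-walk eigenproblem (component indicators are
  # then piecewise constant).
  coords <- vecs[, keep, drop = FALSE] * ifelse(deg > 0, 1 / sqrt(deg), 0)
  structure(list(coords = coords,
                 values = vals[keep],
                 vectors = vecs[, keep, drop = FALSE],
                 X_train = X, degrees = deg, knn = knn, d = d),
            class = "spectral_embedding")
}

#' Nystrom out-of-sample extension of a spectral embedding
#'
#' Maps new samples into a fitted embedding by the Nystrom extension of the
#' random-walk eigenproblem: each new point is connected to its `knn`
#' nearest training points with binary affinities `b`, and its coordinate
#' along eigenfunction `f_j` is `f_j(x) = (1 / sigma_j) * sum_i (b_i / d_x)
#' f_j(i)` with `sigma_j = 1 - lambda_j`.
#'
#' @param object a fitted `spectral_embedding`.
#' @param newdata `m x s` matrix in the same feature space as the training X.
#' @param ... unused.
#' @return `m x d` matrix of embedded coordinates.
#' @export
predict.spectral_embedding <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  nt <- nrow(object$X_train)
  m <- nrow(newdata)
  sigma <- pmax(1 - object$values, 1e-9)   # affinity-operator eigenvalues
  out <- matrix(0, m, object$d)
  tr_norm <- rowSums(object$X_train^2)
  for (i in seq_len(m)) {
    dd <- tr_norm - 2 * as.vector(object$X_train %*% newdata[i, ])
    nb <- order(dd)[seq_len(object$knn)]
    b <- numeric(nt)
    b[nb] <- 1
    out[i, ] <- ((b / sum(b)) %*% object$coords) / sigma
  }
  out
}

#' Serial fusion: column-wise concatenation of feature matrices
#'
#' @param embeddings ordered list of matrices sharing row count/order.
#' @return fused matrix of width `sum(widths)` with a `"widths"` attribute.
#' @export
serial_fuse <- function(embeddings) {
  if (!length(embeddings)) stop("serial_fuse(): no inputs")
  ns <- vapply(embeddings, nrow, 0L)
  if (length(unique(ns)) != 1L) {
    nm <- names(embeddings)
    if (is.null(nm)) nm <- paste0("source", seq_along(embeddings))
    stop(sprintf("serial_fuse(): row counts differ (%s)",
                 paste(sprintf("%s: %d", nm, ns), collapse = ", ")))
  }
  fused <- do.call(cbind, lapply(embeddings, unname))
  attr(fused, "widths") <- vapply(embeddings, ncol, 0L)
  attr(fused, "sources") <- names(embeddings)
  fused
}

# Table of combination codes: which single-model sources feed each fusion.
fusion_code_table <- function() {
  list(C1 = "resnet50v2", C2 = "densenet121", C3 = "inception_v3",
       C4 = "inception_resnet",
       C5 = c("C1", "C2"), C6 = c("C1", "C3"), C7 = c("C1", "C4"),
       C8 = c("C2", "C3"), C9 = c("C2", "C4"), C10 = c("C3", "C4"),
       C11 = c("C1", "C2", "C3"), C12 = c("C1", "C2", "C4"),
       C13 = c("C2", "C3", "C4"), C14 = c("C1", "C2", "C3", "C4"),
       TIF = "tif", VGG19 = "vgg19", LBP = "lbp", HOG = "hog")
}

#' Fusion specification for a combination code
#'
#' Maps the combination codes to their ordered source lists: C1-C4 are the
#' four single backbones (ResNet50 v2, DenseNet121, Inception v3,
#' Inception-ResNet), C5-C14 their pairwise to four-way serial fusions, and
#' TIF/LBP/HOG/VGG19 the remaining single sources. Each fused source is
#' reduced to `dim_per_source` embedding dimensions before concatenation, so
#' the default 200 reproduces the published fused lengths (two sources ->
#' 400, three -> 600, four -> 800).
#'
#' @param code a combination code, e.g. `"C5"`.
#' @param dim_per_source per-source embedding dimension.
#' @param sources optional explicit character vector of source names,
#'   overriding the code table (for ad-hoc fusions of user feature sets).
#' @return object of class `fusion_spec` with `code`, `sources` (single-model
#'   names), `dim_per_source` and `fused_width`.
#' @export
fusion_spec <- function(code, dim_per_source = 200L, sources = NULL) {
  if (is.null(sources)) {
    tab <- fusion_code_table()
    if (!code %in% names(tab)) {
      stop(sprintf("unknown combination code '%s'; known: %s", code,
                   paste(names(tab), collapse = ", ")))
    }
    entry <- tab[[code]]
    sources <- unlist(lapply(entry, function(e) if (e %in% names(tab)) tab[[e]] else e))
  }
  structure(list(code = code, sources = sources,
                 dim_per_source = as.integer(dim_per_source),
                 fused_width = length(sources) * as.integer(dim_per_source)),
            class = "fusion_spec")
}

#' ANOVA-F / spectral-embedding fusion pipeline
#'
#' For each feature source in `spec`: score features with [anova_f()],
#' keep the cumulative-99.9% subset with [select_features()], embed the
#' selection to `spec$dim_per_source` coordinates with [spectral_embed()],
#' then serially fuse the per-source embeddings with [serial_fuse()].
#' With `mode = "nystrom"` (default) the embedding is fitted on the training
#' rows and test rows are mapped by the Nystrom extension; `"transductive"`
#' embeds train and test jointly.
#'
#' @param feature_sets named list of `n x s_i` matrices, one per source named
#'   in `spec$sources` (extra entries are ignored).
#' @param y training labels (one per row).
#' @param spec a [fusion_spec()].
#' @param test_sets optional named list of test feature matrices with the
#'   same sources and column counts.
#' @param threshold cumulative selection threshold.
#' @param knn affinity-graph neighbourhood size.
#' @param mode out-of-sample strategy, `"nystrom"` or `"transductive"`.
#' @return object of class `afse_fusion`: `fused` (training matrix of width
#'   `spec$fused_width`), `fused_test` (when `test_sets` given), and a
#'   per-source `report` (features kept, eigenvalue spectrum).
#' @export
afse_pipeline <- function(feature_sets, y, spec, test_sets = NULL,
                          threshold = 0.999, knn = 10L,
                          mode = c("nystrom", "transductive")) {
  mode <- match.arg(mode)
  missing <- setdiff(spec$sources, names(feature_sets))
  if (length(missing)) {
    stop(sprintf("feature_sets lacks source(s): %s", paste(missing, collapse = ", ")))
  }
  embeds <- list(); embeds_test <- list(); report <- list()
  for (src in spec$sources) {
    X <- as.matrix(feature_sets[[src]])
    res <- anova_f(X, y)
    keep <- select_features(res, threshold)
    Xs <- X[, keep, drop = FALSE]
    Xt <- if (!is.null(test_sets)) as.matrix(test_sets[[src]])[, keep, drop = FALSE]
    if (mode == "transductive" && !is.null(Xt)) {
      emb <- spectral_embed(rbind(Xs, Xt), spec$dim_per_source, knn)
      embeds[[src]] <- emb$coords[seq_len(nrow(Xs)), , drop = FALSE]
      embeds_test[[src]] <- emb$coords[nrow(Xs) + seq_len(nrow(Xt)), , drop = FALSE]
    } else {
      emb <- spectral_embed(Xs, spec$dim_per_source, knn)
      embeds[[src]] <- emb$coords
      if (!is.null(Xt)) embeds_test[[src]] <- predict(emb, Xt)
    }
    report[[src]] <- list(n_features = ncol(X), n_kept = length(keep),
                          kept = keep, eigenvalues = emb$values)
  }
  structure(list(fused = serial_fuse(embeds),
                 fused_test = if (length(embeds_test)) serial_fuse(embeds_test),
                 spec = spec, report = report, mode = mode),
            class = "afse_fusion")
}
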