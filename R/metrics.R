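# Feature-quality diagnostics: chi-square scores, ANOVA-F weights,
# extremely-randomized-trees importances, normalized descending weight
# curves and sparsity.

#' Chi-square relevance scores
#'
#' For each (non-negative) feature, sums the feature mass within each class
#' (observed `A`), compares it with the expectation `T` under independence
#' from the class (class prior times total feature mass), and returns
#' `chi2 = sum (A - T)^2 / T`. Zero exactly when the class-conditional sums
#' match the expectation.
#'
#' @param X `n x s` non-negative feature matrix (count/frequency semantics).
#' @param y class labels, one per row.
#' @return per-feature score vector of length `s`.
#' @export
chi2_scores <- function(X, y) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("chi2_scores() requires non-negative features")
  y <- as.integer(factor(y))
  k <- max(y)
  obs <- rowsum(X, y)                       # k x s class-conditional sums
  prior <- tabulate(y, k) / nrow(X)
  expd <- prior %o% colSums(X)
  dev <- (obs - expd)^2
  ratio <- ifelse(expd > 0, dev / expd, 0)
  colSums(ratio)
}

#' Extremely-randomized-trees feature importance
#'
#' Mean impurity-decrease importance from an extremely randomized trees
#' ensemble (random split points, no bootstrap), normalized to sum to one.
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param n_trees ensemble size.
#' @param seed RNG seed for the ensemble.
#' @return non-negative importance vector of length `ncol(X)` summing to 1.
#' @export
et_importance <- function(X, y, n_trees = 100L, seed = 1L) {
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = as.data.frame(X), y = factor(y),
                        num.trees = n_trees, splitrule = "extratrees",
                        num.random.splits = 1L, replace = FALSE,
                        sample.fraction = 1, importance = "impurity",
                        seed = seed, num.threads = 1L)
  imp <- pmax(unname(fit$variable.importance), 0)
  normalize_f(imp)
}

#' Normalized descending weight curve and sparsity
#'
#' Normalizes a score vector to weights summing to one, sorts it in
#' descending order (the curves plotted for feature-quality comparison), and
#' reports sparsity as the fraction of features whose normalized weight
#' falls below `epsilon`.
#'
#' @param scores non-negative score vector.
#' @param epsilon sparsity cut-off on the normalized weight.
#' @return list with `weights` (normalized, original order), `curve`
#'   (descending) and `sparsity`.
#' @export
weight_curve <- function(scores, epsilon = 1e-6) {
  w <- normalize_f(scores)
  list(weights = w, curve = sort(w, decreasing = TRUE),
       sparsity = mean(w < epsilon))
}

#' Feature-quality report
#'
#' Computes chi-square, ANOVA-F and extremely-randomized-trees scores for a
#' labelled feature matrix, normalizes each to a weight curve and attaches
#' its sparsity. Features are min-max scaled to `[0, 1]` before the
#' chi-square test (which requires non-negative inputs).
#'
#' @param X feature matrix.
#' @param y class labels.
#' @param n_trees,seed passed to [et_importance()].
#' @param epsilon sparsity cut-off (see [weight_curve()]).
#' @return object of class `feature_weight_report`: a list of `chi2`, `anova`
#'   and `et` weight curves plus a `sparsity` summary.
#' @export
feature_weight_report <- function(X, y, n_trees = 100L, seed = 1L, epsilon = 1e-6) {
  X <- as.matrix(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  Xs <- sweep(X, 2, rng[1, ])
  Xs[, span > 0] <- sweep(Xs[, span > 0, drop = FALSE], 2, span[span > 0], `/`)
  curves <- list(chi2 = weight_curve(chi2_scores(Xs, y), epsilon),
                 anova = weight_curve(anova_f(X, y)$f, epsilon),
                 et = weight_curve(et_importance(X, y, n_trees, seed), epsilon))
  structure(c(curves,
              list(sparsity = vapply(curves, `[[`, 0, "sparsity"),
                   epsilon = epsilon)),
            class = "feature_weight_report")
}

#' Gini coefficient of a weight vector
#'
#' Inequality of a (normalized) weight curve: 0 for perfectly balanced
#' weights, approaching 1 when mass concentrates on few features. Used to
#' compare how quickly deep-feature and handcrafted weight curves decay.
#'
#' @param w non-negative weights.
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini_coefficient <- function(w) {
  w <- sort(w)
  n <- length(w)
  if (sum(w) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * w) / (n * sum(w))
}
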