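#' Rank features by a two-class pooled-variance t criterion
#'
#' For each feature, computes the absolute two-sample t statistic with
#' pooled variance, `|m1 - m0| / (s_p * sqrt(1/n0 + 1/n1))`, between the
#' class-0 and class-1 rows, and orders features by decreasing criterion.
#' The criterion is scale-invariant, so ranking does not depend on feature
#' units. Ties are broken by the canonical feature order. Ranking is
#' reported for interpretation only; all 17 features are passed on to the
#' PCA stage regardless of rank.
#'
#' @param features A data frame containing the 17 feature columns and a
#'   class column.
#' @param class_col Name of the 0/1 class column.
#' @param feature_cols Feature columns to rank.
#' @return A tibble with columns `feature`, `criterion`, `rank`, sorted by
#'   decreasing criterion.
#' @export
rank_features <- function(features, class_col = "class",
                          feature_cols = feature_names()) {
  stopifnot(is.data.frame(features), class_col %in% names(features))
  y <- features[[class_col]]
  if (length(unique(y)) != 2L) stop("ranking requires exactly two classes")
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  if (n0 < 2L || n1 < 2L) stop("each class needs at least 2 rows")
  crit <- vapply(feature_cols, function(f) {
    x0 <- features[[f]][y == 0]
    x1 <- features[[f]][y == 1]
    sp2 <- ((n0 - 1) * stats::var(x0) + (n1 - 1) * stats::var(x1)) /
      (n0 + n1 - 2)
    if (sp2 == 0) {
      if (mean(x1) == mean(x0)) 0 else Inf
    } else {
      abs(mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n0 + 1 / n1))
    }
  }, numeric(1))
  crit <- unname(crit)
  ord <- order(-crit, match(feature_cols, feature_names()))
  tibble::tibble(feature = feature_cols[ord], criterion = crit[ord],
                 rank = seq_along(ord))
}

#' Fit a variance-thresholded PCA projection
#'
#' Centers (and by default z-scores) the feature columns and fits a
#' principal component analysis, retaining the minimal number of components
#' `k` whose cumulative explained variance reaches `var_threshold`.
#' Z-scoring is the default because the 17 features mix units (uV^2, uV,
#' dimensionless); `scale = FALSE` gives a covariance (center-only) PCA.
#' Loading signs are fixed by making each vector's largest-magnitude entry
#' positive. Constant columns are centered but given unit scale so they
#' contribute zero variance rather than NaNs.
#'
#' @param features A data frame containing the feature columns.
#' @param var_threshold Explained-variance threshold in (0, 1].
#' @param scale Z-score features before PCA?
#' @param feature_cols Feature columns to project.
#' @return An object of class `lfp_projection` with elements `center`,
#'   `scale`, `rotation` (all components), `k`, `explained` (per-component
#'   variance fractions) and `var_threshold`.
#' @export
fit_projection <- function(features, var_threshold = 0.99, scale = TRUE,
                           feature_cols = feature_names()) {
  stopifnot(var_threshold > 0, var_threshold <= 1)
  X <- as.matrix(features[, feature_cols, drop = FALSE])
  if (anyNA(X)) stop("feature matrix contains missing values")
  ctr <- colMeans(X)
  scl <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  if (all(abs(Z) < .Machine$double.eps^0.5)) {
    stop("feature matrix has zero variance: nothing to project")
  }
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  explained <- ev / sum(ev)
  k <- which(cumsum(explained) >= var_threshold - 1e-12)[1L]
  # deterministic sign: largest-magnitude loading entry positive
  rot <- pc$rotation
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(feature_cols = feature_cols, center = ctr, scale = scl,
         rotation = rot, explained = explained, k = k,
         var_threshold = var_threshold, scaled = scale),
    class = "lfp_projection"
  )
}

#' @export
print.lfp_projection <- function(x, ...) {
  cat(sprintf(
    "<lfp_projection> %d features -> k = %d components (%.2f%% variance, threshold %.0f%%)\n",
    length(x$feature_cols), x$k, 100 * sum(x$explained[seq_len(x$k)]),
    100 * x$var_threshold))
  invisible(x)
}

#' Project new rows with a fitted projection
#'
#' Applies the training-time centering/scaling constants and loadings to
#' new rows; the projection is never refitted on prediction data.
#'
#' @param object An `lfp_projection`.
#' @param newdata A data frame containing the training feature columns.
#' @param k Number of components to return (default: the fitted `k`).
#' @param ... Unused.
#' @return A tibble of component scores `PC1..PCk`.
#' @export
predict.lfp_projection <- function(object, newdata, k = object$k, ...) {
  miss <- setdiff(object$feature_cols, names(newdata))
  if (length(miss) > 0L) {
    stop("newdata is missing feature column(s): ", paste(miss, collapse = ", "))
  }
  X <- as.matrix(newdata[, object$feature_cols, drop = FALSE])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  S <- Z %*% object$rotation[, seq_len(k), drop = FALSE]
  colnames(S) <- paste0("PC", seq_len(k))
  tibble::as_tibble(S)
}

#' @rdname predict.lfp_projection
#' @param projection An `lfp_projection`.
#' @export
apply_projection <- function(projection, newdata, k = projection$k) {
  predict.lfp_projection(projection, newdata, k = k)
}
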