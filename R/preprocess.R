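#' Keep samples with an acceptable fraction of missing values
#'
#' @param X Matrix possibly containing `NA`s (samples in rows).
#' @param max_missing_fraction Maximum tolerated missing fraction per row;
#'   rows strictly above it are dropped.
#' @return Logical row mask (`TRUE` = keep).
#' @export
filter_samples <- function(X, max_missing_fraction = 0.2) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  frac <- rowMeans(is.na(X))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop("all samples exceed the missing-value threshold")
  keep
}

#' Standardize features to zero mean and unit standard deviation
#'
#' Column means and population (ddof = 0) standard deviations are estimated
#' on `X_train` and the same affine transform is applied to `X_apply`.
#' Zero-variance features are mapped to all-zeros and flagged.
#'
#' @param X_train Training matrix (samples in rows).
#' @param X_apply Optional matrix to transform with the training parameters.
#' @return List with `train`, `apply` (or `NULL`), `center`, `scale`, and
#'   `zero_variance` (logical flag per feature).
#' @export
standardize <- function(X_train, X_apply = NULL) {
  center <- colMeans(X_train)
  scale <- sqrt(colMeans(sweep(X_train, 2, center)^2))
  zero_variance <- scale == 0
  scale_safe <- ifelse(zero_variance, 1, scale)
  transform <- function(M) {
    M <- sweep(sweep(M, 2, center), 2, scale_safe, `/`)
    M[, zero_variance] <- 0
    M
  }
  list(train = transform(X_train),
       apply = if (!is.null(X_apply)) transform(X_apply),
       center = center, scale = scale, zero_variance = zero_variance)
}

new_feature_selection <- function(scores, k, method) {
  ord <- order(-scores, seq_along(scores))
  structure(list(selected_indices = ord[seq_len(k)], scores = scores,
                 method = method),
            class = "feature_selection")
}

#' Select top-k features by one-way ANOVA F between label classes
#'
#' The F statistic is computed per feature on the supplied (training)
#' samples only; the top `k` by descending F are retained, ties broken by
#' ascending feature index.
#'
#' @param X_train Matrix of training samples.
#' @param y_train Class label per training sample (2+ classes required).
#' @param k Number of features to keep.
#' @return A `feature_selection` (fields `selected_indices`, `scores`,
#'   `method`).
#' @export
select_anova_f <- function(X_train, y_train, k) {
  stopifnot(k <= ncol(X_train))
  y_train <- as.factor(y_train)
  g <- nlevels(y_train)
  if (g < 2) stop("y_train must contain at least two classes")
  n <- nrow(X_train)
  grand <- colMeans(X_train)
  ssb <- numeric(ncol(X_train))
  ssw <- numeric(ncol(X_train))
  for (lev in levels(y_train)) {
    rows <- y_train == lev
    m <- colMeans(X_train[rows, , drop = FALSE])
    ssb <- ssb + sum(rows) * (m - grand)^2
    ssw <- ssw + colSums(sweep(X_train[rows, , drop = FALSE], 2, m)^2)
  }
  f <- (ssb / (g - 1)) / (ssw / (n - g))
  f[ssw == 0 & ssb == 0] <- 0
  new_feature_selection(f, k, "anova_f")
}

#' Select top-k features by mean absolute deviation
#'
#' Label-free selection by the mean absolute deviation of each feature about
#' its mean (not the median-based `stats::mad`).
#'
#' @param X Matrix (all samples may be used; selection is unsupervised).
#' @param k Number of features to keep.
#' @return A `feature_selection`.
#' @export
select_mad <- function(X, k) {
  stopifnot(k <= ncol(X))
  scores <- colMeans(abs(sweep(X, 2, colMeans(X))))
  new_feature_selection(scores, k, "mad")
}

#' Normalize each sample (row) to unit Euclidean norm
#'
#' Required before CCSA domain adaptation, which measures pairwise Euclidean
#' distances in the embedding space.
#'
#' @param X Matrix (samples in rows).
#' @return Matrix whose rows each satisfy `sum(x^2) == 1`.
#' @export
l2_normalize_rows <- function(X) {
  norms <- sqrt(rowSums(X^2))
  bad <- which(norms == 0)
  if (length(bad) > 0) {
    id <- if (!is.null(rownames(X))) rownames(X)[bad[1]] else bad[1]
    stop("cannot L2-normalize all-zero sample row: ", id)
  }
  X / norms
}

#' Fold-wise preprocessing without leakage
#'
#' Standardizes using training rows only and (when `k < ncol(X)`) selects the
#' top-k ANOVA-F features on the training rows, then applies both to the
#' held-out rows. With `k >= ncol(X)` no selection is performed.
#'
#' @param X Full matrix; `y` full label vector.
#' @param train_idx Row indices of the training fold(s).
#' @param test_idx Row indices of the held-out fold.
#' @param k Number of features to keep (default: all).
#' @return List with `X_train`, `X_test`, `selection` (or `NULL`).
#' @export
preprocess_fold <- function(X, y, train_idx, test_idx, k = ncol(X)) {
  std <- standardize(X[train_idx, , drop = FALSE], X[test_idx, , drop = FALSE])
  sel <- NULL
  Xtr <- std$train
  Xte <- std$apply
  if (k < ncol(X)) {
    sel <- select_anova_f(Xtr, y[train_idx], k)
    Xtr <- Xtr[, sel$selected_indices, drop = FALSE]
    Xte <- Xte[, sel$selected_indices, drop = FALSE]
  }
  list(X_train = Xtr, X_test = Xte, selection = sel)
}
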