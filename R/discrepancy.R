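#' Permutation t-test for differential expression between groups
#'
#' Per feature, a two-sample t statistic (Welch by default) between the two
#' groups; significance is assessed against `n_permutations` random
#' permutations of the group labels, shared across features (one permutation
#' matrix), with the smoothed p-value
#' `p = (1 + #\{|t*| >= |t|\}) / (1 + B)`.
#'
#' @param X Feature matrix (samples in rows).
#' @param group Group id per sample in `{1, 2}`.
#' @param n_permutations Number of permutations `B` (> 0).
#' @param alpha Feature-wise significance level for the DE mask.
#' @param var_equal Pooled-variance t statistic instead of Welch.
#' @param seed Integer seed for the permutations.
#' @return List with `p_values`, `t_obs`, `de_mask`, `de_fraction`.
#' @export
permutation_ttest <- function(X, group, n_permutations = 1000, alpha = 0.05,
                              var_equal = FALSE, seed = 1L) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  g1 <- group == 1L
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")
  n <- n1 + n2

  tstat_from_indicator <- function(ind) {
    # ind: n x B matrix of 0/1 group-1 membership indicators
    s1 <- crossprod(ind, X)                       # B x p sums, group 1
    s1sq <- crossprod(ind, X^2)
    s2 <- matrix(colSums(X), nrow(s1), ncol(X), byrow = TRUE) - s1
    s2sq <- matrix(colSums(X^2), nrow(s1), ncol(X), byrow = TRUE) - s1sq
    m1 <- s1 / n1
    m2 <- s2 / n2
    v1 <- (s1sq - n1 * m1^2) / (n1 - 1)
    v2 <- (s2sq - n2 * m2^2) / (n2 - 1)
    if (var_equal) {
      sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)
      (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
    } else {
      (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
    }
  }

  obs <- tstat_from_indicator(matrix(as.numeric(g1), ncol = 1))
  t_obs <- as.numeric(obs)

  set.seed(derive_seed(seed, 11))
  perm_ind <- replicate(n_permutations, {
    ind <- numeric(n)
    ind[sample.int(n, n1)] <- 1
    ind
  })
  t_perm <- abs(tstat_from_indicator(perm_ind))   # B x p
  exceed <- colSums(t_perm >= matrix(abs(t_obs), n_permutations, ncol(X),
                                     byrow = TRUE))
  p <- (1 + exceed) / (1 + n_permutations)
  list(p_values = p, t_obs = t_obs, de_mask = p < alpha,
       de_fraction = mean(p < alpha))
}

#' Per-group multivariate logistic regression coefficients
#'
#' Fits one ridge-penalized multivariate logistic regression per group
#' (all features jointly; a small penalty keeps the fit identifiable when
#' features rival samples or classes are separable) and returns the
#' coefficient vectors without intercepts.
#'
#' @param X Feature matrix; `y` labels in `{-1, +1}` or `{0, 1}`; `group`
#'   group ids in `{1, 2}`.
#' @param y,group See above.
#' @param ridge Ridge penalty (glmnet `lambda` with `alpha = 0`).
#' @return List with `beta_group1`, `beta_group2`.
#' @export
group_logistic <- function(X, y, group, ridge = 1e-4) {
  y01 <- as_y01(y)
  fit_one <- function(g) {
    rows <- group == g
    yy <- y01[rows]
    if (length(unique(yy)) < 2)
      stop("group ", g, " contains a single outcome class; logistic fit ",
           "undefined")
    fit <- glmnet::glmnet(X[rows, , drop = FALSE], yy, family = "binomial",
                          alpha = 0, lambda = ridge, standardize = FALSE,
                          maxit = 1e6, thresh = 1e-12)
    as.numeric(fit$beta)
  }
  list(beta_group1 = fit_one(1L), beta_group2 = fit_one(2L))
}

#' Pearson correlation between two coefficient vectors
#'
#' @param beta1,beta2 Equal-length numeric vectors (length >= 3, each with
#'   nonzero variance).
#' @return Pearson correlation coefficient.
#' @export
coefficient_correlation <- function(beta1, beta2) {
  if (length(beta1) != length(beta2)) stop("vectors must have equal length")
  if (length(beta1) < 3) stop("need at least 3 coefficients")
  if (sd(beta1) == 0 || sd(beta2) == 0)
    stop("correlation undefined for a constant coefficient vector")
  cor(beta1, beta2)
}

#' Marginal and conditional discrepancy report for a two-group cohort
#'
#' Quantifies the marginal discrepancy as the fraction of features
#' differentially expressed between the groups (permutation t-test) and the
#' conditional discrepancy via the Pearson correlation of the per-group
#' multivariate logistic regression coefficients.
#'
#' @param cohort A `cohort` (or list with `X`, `y`, `group`).
#' @param n_permutations,alpha Passed to [permutation_ttest()].
#' @param ridge Passed to [group_logistic()].
#' @param seed Permutation seed.
#' @return Object of class `discrepancy_report`.
#' @export
discrepancy_report <- function(cohort, n_permutations = 1000, alpha = 0.05,
                               ridge = 1e-4, seed = 1L) {
  de <- permutation_ttest(cohort$X, cohort$group, n_permutations, alpha,
                          seed = seed)
  betas <- group_logistic(cohort$X, cohort$y, cohort$group, ridge)
  structure(list(de_fraction = de$de_fraction, de_pvalues = de$p_values,
                 beta_group1 = betas$beta_group1,
                 beta_group2 = betas$beta_group2,
                 pearson_r = coefficient_correlation(betas$beta_group1,
                                                     betas$beta_group2),
                 alpha = alpha),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat(sprintf("<discrepancy_report> DE fraction %.3f (alpha %.2f) | beta correlation r = %.3f\n",
              x$de_fraction, x$alpha, x$pearson_r))
  invisible(x)
}
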