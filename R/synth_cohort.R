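#' Configuration of the synthetic two-group cohort generator
#'
#' Bundles every parameter of the generative model for a two-group labelled
#' expression cohort. Data inequality is controlled by the group sizes `n1`
#' (majority) and `n2` (minority); marginal distribution discrepancy by the
#' number of differentially expressed features `n_de`; conditional
#' discrepancy by the four counts of group-specific feature-effect sign
#' combinations `beta_counts`.
#'
#' @param n1,n2 Number of samples in group 1 (majority) and group 2
#'   (minority).
#' @param n_features Total number of expression features.
#' @param n_de Number of differentially expressed features (group-2 mean
#'   shifted on the count scale).
#' @param beta_counts Integer vector of length 4, counts of features whose
#'   effect-sign pair `(beta1, beta2)` is `(-1,-1)`, `(-1,+1)`, `(+1,-1)`,
#'   `(+1,+1)`; must sum to `n_features`.
#' @param de_fold_change Multiplicative shift applied to the group-2 mean of
#'   DE features before log transformation (direction randomised per
#'   feature). Dimensionless, > 0.
#' @param dispersion Negative-binomial overdispersion of the count model
#'   (variance `mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param class_quantile Quantile of the per-group logistic score used as the
#'   class threshold `c^k`; `0.5` gives balanced classes.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return An object of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(n1 = 50, n2 = 20, n_features = 30, n_de = 5,
#'                         beta_counts = c(10, 5, 5, 10))
synthetic_config <- function(n1, n2, n_features = 200, n_de = 0,
                             beta_counts = c(n_features, 0, 0, 0),
                             de_fold_change = 2, dispersion = 0.1,
                             class_quantile = 0.5, seed = 1L) {
  stopifnot(length(beta_counts) == 4)
  if (n1 < 1 || n2 < 1) stop("group sizes n1 and n2 must both be >= 1")
  if (n_de < 0 || n_de > n_features)
    stop("n_de must lie in [0, n_features]; got ", n_de)
  if (sum(beta_counts) != n_features)
    stop("beta_counts must sum to n_features (", n_features, "); got ",
         sum(beta_counts))
  if (any(beta_counts < 0)) stop("beta_counts must be non-negative")
  if (de_fold_change <= 0) stop("de_fold_change must be > 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (class_quantile <= 0 || class_quantile >= 1)
    stop("class_quantile must lie strictly in (0, 1)")
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2),
         n_features = as.integer(n_features), n_de = as.integer(n_de),
         beta_counts = as.integer(beta_counts),
         de_fold_change = de_fold_change, dispersion = dispersion,
         class_quantile = class_quantile, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Canonical synthetic dataset configurations
#'
#' The four study conditions of the synthetic benchmark: dataset 1 has both
#' data inequality (2184 vs 320 samples) and distribution discrepancy
#' (20 DE features, 74 of 200 discordant effect signs); dataset 2 keeps the
#' inequality but removes the discrepancy; dataset 3 keeps the discrepancy
#' with equal group sizes (260 each); dataset 4 has neither.
#'
#' @param dataset Integer 1-4.
#' @param seed Seed passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
synthetic_data_config <- function(dataset, seed = 1L) {
  pars <- switch(as.character(dataset),
    "1" = list(n1 = 2184L, n2 = 320L, n_de = 20L, bc = c(64L, 37L, 37L, 62L)),
    "2" = list(n1 = 2184L, n2 = 320L, n_de = 0L,  bc = c(100L, 0L, 0L, 100L)),
    "3" = list(n1 = 260L,  n2 = 260L, n_de = 20L, bc = c(64L, 37L, 37L, 62L)),
    "4" = list(n1 = 260L,  n2 = 260L, n_de = 0L,  bc = c(100L, 0L, 0L, 100L)),
    stop("dataset must be 1, 2, 3 or 4"))
  synthetic_config(n1 = pars$n1, n2 = pars$n2, n_features = 200L,
                   n_de = pars$n_de, beta_counts = pars$bc, seed = seed)
}

#' Simulate the expression feature matrix
#'
#' Draws negative-binomial counts with log-normal baseline means (log-mean 5,
#' log-sd 1 on the natural-log scale) shared by the two groups; for `n_de`
#' randomly chosen features the group-2 mean is multiplied by
#' `de_fold_change` (direction randomised per feature) before sampling.
#' Counts are transformed as `log2(count + 1)`. Standardisation is left to
#' the caller so the marginal shift is visible on the log scale.
#'
#' @param config A [synthetic_config()].
#' @return List with `X` (matrix, `(n1+n2) x n_features`), `group`
#'   (integer vector in `{1, 2}`), and `de_idx` (indices of DE features).
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 101))
  p <- config$n_features
  n <- config$n1 + config$n2
  group <- rep(1:2, c(config$n1, config$n2))
  mu <- exp(rnorm(p, mean = 5, sd = 1))
  de_idx <- if (config$n_de > 0) sort(sample.int(p, config$n_de)) else integer(0)
  fc <- rep(1, p)
  if (config$n_de > 0) {
    direction <- sample(c(-1, 1), config$n_de, replace = TRUE)
    fc[de_idx] <- config$de_fold_change^direction
  }
  mu_mat <- matrix(mu, n, p, byrow = TRUE)
  mu_mat[group == 2L, ] <- sweep(mu_mat[group == 2L, , drop = FALSE], 2, fc, `*`)
  counts <- if (config$dispersion > 0) {
    matrix(rnbinom(n * p, mu = mu_mat, size = 1 / config$dispersion), n, p)
  } else {
    matrix(stats::rpois(n * p, lambda = mu_mat), n, p)
  }
  list(X = log2(counts + 1), group = group, de_idx = de_idx)
}

#' Assign group-specific feature-effect signs
#'
#' Distributes the four `(beta1, beta2)` sign combinations over feature
#' positions by a uniform random permutation under the configuration seed.
#'
#' @param config A [synthetic_config()].
#' @return List of class `beta_pair` with `beta1`, `beta2` (vectors of
#'   `-1`/`+1` of length `n_features`).
#' @export
assign_betas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 102))
  combos <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  combo_id <- sample(rep.int(1:4, config$beta_counts))
  structure(list(beta1 = combos[combo_id, 1], beta2 = combos[combo_id, 2]),
            class = "beta_pair")
}

#' Logistic score of one sample
#'
#' `z = 1 / (1 + exp(-sum(beta * x)))`, the probability-scale score used to
#' assign outcome labels.
#'
#' @param x Feature vector of one sample.
#' @param beta Effect vector of the sample's group, same length.
#' @return Scalar in (0, 1).
#' @export
logistic_score <- function(x, beta) {
  if (length(x) != length(beta))
    stop("x and beta must have the same length (", length(x), " vs ",
         length(beta), ")")
  plogis(sum(beta * x))
}

#' Generate outcome labels from logistic scores
#'
#' Per group `k`, the threshold `c^k` is the `class_quantile` quantile of the
#' group's logistic scores; a sample is labelled `+1` iff its score strictly
#' exceeds `c^k`, else `-1`.
#'
#' @param X Standardized feature matrix.
#' @param group Group id per row, in `{1, 2}`.
#' @param betas A `beta_pair` from [assign_betas()].
#' @param class_quantile Threshold quantile in (0, 1).
#' @return List with `y` (labels in `{-1, +1}`), `thresholds` (named c1, c2),
#'   and `z` (the scores).
#' @export
generate_labels <- function(X, group, betas, class_quantile = 0.5) {
  stopifnot(nrow(X) == length(group))
  beta_mat <- cbind(betas$beta1, betas$beta2)
  z <- numeric(nrow(X))
  thresholds <- numeric(2)
  y <- integer(nrow(X))
  for (k in 1:2) {
    rows <- which(group == k)
    if (length(rows) == 0) stop("group ", k, " has zero samples")
    zk <- plogis(as.vector(X[rows, , drop = FALSE] %*% beta_mat[, k]))
    ck <- unname(quantile(zk, class_quantile))
    z[rows] <- zk
    thresholds[k] <- ck
    y[rows] <- ifelse(zk > ck, 1L, -1L)
  }
  names(thresholds) <- c("c1", "c2")
  list(y = y, thresholds = thresholds, z = z)
}

#' Generate a complete synthetic cohort
#'
#' Composes feature simulation, standardisation (population-sd convention),
#' effect-sign assignment, and label generation. The ground truth (DE feature
#' indices, effect-sign vectors, thresholds, configuration) is recorded under
#' `$truth`.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `cohort`: list with `X` (standardized matrix
#'   with sample/feature dimnames), `y` (`-1`/`+1`), `group` (`1`/`2`),
#'   `feature_ids`, `sample_ids`, `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  sim <- simulate_features(config)
  std <- standardize(sim$X)
  betas <- assign_betas(config)
  lab <- generate_labels(std$train, sim$group, betas, config$class_quantile)
  feature_ids <- sprintf("feature_%03d", seq_len(config$n_features))
  sample_ids <- sprintf("sample_%04d", seq_len(nrow(std$train)))
  X <- std$train
  dimnames(X) <- list(sample_ids, feature_ids)
  structure(
    list(X = X, y = lab$y, group = sim$group, feature_ids = feature_ids,
         sample_ids = sample_ids,
         truth = list(de_idx = sim$de_idx, beta1 = betas$beta1,
                      beta2 = betas$beta2, thresholds = lab$thresholds,
                      config = config)),
    class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples x %d features | group sizes %d/%d | %d/%d positive labels\n",
              nrow(x$X), ncol(x$X), sum(x$group == 1), sum(x$group == 2),
              sum(x$y == 1), length(x$y)))
  invisible(x)
}

#' Estimate generator parameters from a cohort
#'
#' Reads the group sizes directly, estimates the number of DE features by a
#' permutation t-test between groups (feature-wise p < `alpha`), and derives
#' the effect-sign combination counts by fitting one multivariate ridge
#' logistic regression per group and dichotomising each coefficient at the
#' median of its coefficient vector (`> median` becomes `+1`).
#'
#' @param cohort A `cohort` (or compatible list with `X`, `y`, `group`).
#' @param n_permutations Number of label permutations for the DE test.
#' @param alpha Feature-wise significance level.
#' @param ridge Ridge penalty for the per-group logistic fits.
#' @return A [synthetic_config()] with the estimated parameters (fold change,
#'   dispersion, quantile and seed carried over from defaults).
#' @export
estimate_params_from_cohort <- function(cohort, n_permutations = 1000,
                                        alpha = 0.05, ridge = 1e-4) {
  X <- cohort$X
  y <- cohort$y
  group <- cohort$group
  n1 <- sum(group == 1L)
  n2 <- sum(group == 2L)
  if (n1 == 0 || n2 == 0) stop("cohort must contain samples of both groups")
  de <- permutation_ttest(X, group, n_permutations = n_permutations,
                          alpha = alpha)
  betas <- group_logistic(X, y, group, ridge = ridge)
  s1 <- ifelse(betas$beta_group1 > median(betas$beta_group1), 1L, -1L)
  s2 <- ifelse(betas$beta_group2 > median(betas$beta_group2), 1L, -1L)
  counts <- c(sum(s1 == -1 & s2 == -1), sum(s1 == -1 & s2 == 1),
              sum(s1 == 1 & s2 == -1), sum(s1 == 1 & s2 == 1))
  synthetic_config(n1 = n1, n2 = n2, n_features = ncol(X),
                   n_de = sum(de$de_mask), beta_counts = counts)
}
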