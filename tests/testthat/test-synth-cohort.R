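test_that("configuration invariants are enforced", {
  expect_s3_class(synthetic_config(10, 5, n_features = 8, n_de = 2,
                                   beta_counts = c(2, 2, 2, 2)),
                  "synthetic_config")
  expect_error(synthetic_config(10, 5, n_features = 8, n_de = 9,
                                beta_counts = c(2, 2, 2, 2)), "n_de")
  expect_error(synthetic_config(10, 5, n_features = 8,
                                beta_counts = c(2, 2, 2, 1)), "sum")
  expect_error(synthetic_config(0, 5, n_features = 8,
                                beta_counts = c(2, 2, 2, 2)), "n1")
  expect_error(synthetic_config(10, 5, n_features = 8,
                                beta_counts = c(2, 2, 2, 2),
                                de_fold_change = 0), "de_fold_change")
  expect_error(synthetic_config(10, 5, n_features = 8,
                                beta_counts = c(2, 2, 2, 2),
                                class_quantile = 1), "class_quantile")
})

test_that("simulated feature matrix has the configured shape and DE set", {
  cfg <- synthetic_data_config(1, seed = 4)
  sim <- simulate_features(cfg)
  expect_equal(dim(sim$X), c(2504, 200))
  expect_equal(length(sim$de_idx), 20)
  expect_equal(table(sim$group), table(rep(1:2, c(2184, 320))),
               ignore_attr = TRUE)
})

test_that("without DE features the two groups are exchangeable", {
  # t-test rejection rate across features stays near the nominal 5%
  rejects <- 0
  n_feat <- 0
  for (s in 1:3) {
    cfg <- synthetic_config(n1 = 100, n2 = 100, n_features = 200, n_de = 0,
                            beta_counts = c(100, 0, 0, 100), seed = s)
    sim <- simulate_features(cfg)
    p <- apply(sim$X, 2, function(x)
      t.test(x[sim$group == 1], x[sim$group == 2])$p.value)
    rejects <- rejects + sum(p < 0.05)
    n_feat <- n_feat + length(p)
  }
  # 600 null features at alpha 0.05: binomial 99.9% band around 30
  expect_gt(rejects, 8)
  expect_lt(rejects, 60)
})

test_that("DE features are detectably shifted at the configured fold change", {
  cfg <- synthetic_config(n1 = 260, n2 = 260, n_features = 200, n_de = 20,
                          beta_counts = c(64, 37, 37, 62), seed = 9)
  sim <- simulate_features(cfg)
  p_de <- sapply(sim$de_idx, function(j)
    t.test(sim$X[sim$group == 1, j], sim$X[sim$group == 2, j])$p.value)
  expect_gte(sum(p_de < 0.05), 15)
})

test_that("beta assignment honours the combination counts", {
  cfg <- synthetic_data_config(1, seed = 2)
  bp <- assign_betas(cfg)
  expect_length(bp$beta1, 200)
  counts <- c(sum(bp$beta1 == -1 & bp$beta2 == -1),
              sum(bp$beta1 == -1 & bp$beta2 == 1),
              sum(bp$beta1 == 1 & bp$beta2 == -1),
              sum(bp$beta1 == 1 & bp$beta2 == 1))
  expect_equal(counts, c(64, 37, 37, 62))
  expect_equal(sum(bp$beta1 == bp$beta2), 126)  # concordant positions

  bp2 <- assign_betas(synthetic_data_config(2, seed = 2))
  expect_equal(bp2$beta1, bp2$beta2)

  cfg3 <- synthetic_config(10, 5, n_features = 6, beta_counts = c(6, 0, 0, 0))
  bp3 <- assign_betas(cfg3)
  expect_true(all(bp3$beta1 == -1) && all(bp3$beta2 == -1))
})

test_that("logistic score matches the closed form and its symmetries", {
  expect_equal(logistic_score(c(0, 0, 0), c(1, -1, 1)), 0.5)
  expect_equal(logistic_score(c(1, 1), c(1, 1)), 1 / (1 + exp(-2)),
               tolerance = 1e-12)
  x <- rnorm(5); b <- sample(c(-1, 1), 5, TRUE)
  expect_equal(logistic_score(-x, -b), logistic_score(x, b))
  expect_error(logistic_score(c(1, 2), c(1, 2, 3)), "length")
})

test_that("labels split each group at the class quantile", {
  co <- small_cohort(seed = 3, n1 = 100, n2 = 60)
  for (g in 1:2) {
    yk <- co$y[co$group == g]
    expect_lte(abs(sum(yk == 1) - length(yk) / 2), 1)
  }
  # non-median quantile: positive fraction approximately 1 - q
  cfg <- synthetic_config(n1 = 200, n2 = 200, n_features = 30, n_de = 0,
                          beta_counts = c(15, 0, 0, 15),
                          class_quantile = 0.75, seed = 5)
  co75 <- generate_cohort(cfg)
  for (g in 1:2) {
    yk <- co75$y[co75$group == g]
    expect_lte(abs(sum(yk == 1) - 0.25 * length(yk)), 1)
  }
})

test_that("label generation is deterministic given its inputs and boundary-safe", {
  co <- small_cohort(seed = 6)
  bp <- list(beta1 = co$truth$beta1, beta2 = co$truth$beta2)
  l1 <- generate_labels(co$X, co$group, bp, 0.5)
  l2 <- generate_labels(co$X, co$group, bp, 0.5)
  expect_identical(l1, l2)
  # a quantile at/above the top score leaves at most one positive per group
  lhi <- generate_labels(co$X, co$group, bp, 0.999)
  for (g in 1:2)
    expect_lte(sum(lhi$y[co$group == g] == 1), 1)
  expect_error(generate_labels(co$X, rep(1, nrow(co$X)), bp), "zero samples")
})

test_that("cohort generation is bit-reproducible and carries ground truth", {
  cfg <- synthetic_config(n1 = 80, n2 = 40, n_features = 25, n_de = 3,
                          beta_counts = c(8, 4, 4, 9), seed = 12)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a$truth$de_idx, 3)
  expect_equal(dim(a$X), c(120, 25))
  # equal group sizes under dataset-3/4 style configs
  co3 <- generate_cohort(synthetic_data_config(3, seed = 1))
  expect_equal(sum(co3$group == 1), sum(co3$group == 2))
})

test_that("median dichotomisation maps half the coefficients to -1", {
  v <- rnorm(10)
  s <- ifelse(v > median(v), 1L, -1L)
  expect_equal(sum(s == -1), 5)
})

test_that("parameter estimation recovers group sizes exactly and betas approximately", {
  cfg <- synthetic_config(n1 = 400, n2 = 400, n_features = 100, n_de = 10,
                          beta_counts = c(32, 18, 18, 32), seed = 21)
  co <- generate_cohort(cfg)
  est <- estimate_params_from_cohort(co, n_permutations = 300)
  expect_equal(est$n1, 400L)
  expect_equal(est$n2, 400L)
  # n_de estimate includes alpha-level false positives among the 90 nulls
  expect_gte(est$n_de, 8)
  expect_lte(est$n_de, 10 + 0.05 * 90 + 3 * sqrt(90 * 0.05 * 0.95))
  expect_equal(sum(est$beta_counts), 100)
})

test_that("estimation on exchangeable groups finds ~alpha x n_features DE features", {
  cfg <- synthetic_config(n1 = 150, n2 = 150, n_features = 200, n_de = 0,
                          beta_counts = c(100, 0, 0, 100), seed = 30)
  co <- generate_cohort(cfg)
  de <- permutation_ttest(co$X, co$group, n_permutations = 300)
  # 200 nulls at alpha 0.05: expect about 10, allow a wide binomial band
  expect_gte(sum(de$de_mask), 1)
  expect_lte(sum(de$de_mask), 25)
})
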