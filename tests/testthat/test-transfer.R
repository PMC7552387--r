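# shared toy domain pair: source plentiful, target scarce, same feature space
toy_domains <- function(seed = 1, n_s = 120, n_t = 40, p = 10) {
  co <- generate_cohort(synthetic_config(n1 = n_s, n2 = n_t, n_features = p,
                                         n_de = 0,
                                         beta_counts = c(p / 2, 0, 0, p / 2),
                                         seed = seed))
  idx_t <- which(co$group == 2)
  tr <- idx_t[seq_len(n_t / 2)]
  te <- setdiff(idx_t, tr)
  list(Xs = co$X[co$group == 1, ], ys = co$y[co$group == 1],
       Xt_tr = co$X[tr, ], yt_tr = co$y[tr],
       Xt_te = co$X[te, ], yt_te = co$y[te])
}

quick_spec <- function(p) net_spec(p, hidden = c(16L, 8L))
quick_sda <- function(p) sda_spec(p, hidden = c(16L, 8L, 16L),
                                  max_iter = 40L, seed = 1)

test_that("zero fine-tuning epochs returns the source-only model", {
  d <- toy_domains()
  fit0 <- finetune_transfer(d$Xs, d$ys, d$Xt_tr, d$yt_tr, quick_spec(10),
                            pretrain_cfg = quick_train(seed = 5),
                            finetune_cfg = train_config(lr = 0.002,
                                                        batch_size = 10L,
                                                        max_iter = 0L,
                                                        seed = 5))
  src <- mlp_train(d$Xs, d$ys, quick_spec(10), quick_train(seed = 5))
  expect_identical(fit0$W, src$W)
  ft <- finetune_transfer(d$Xs, d$ys, d$Xt_tr, d$yt_tr, quick_spec(10),
                          pretrain_cfg = quick_train(seed = 5),
                          finetune_cfg = train_config(lr = 0.002,
                                                      batch_size = 10L,
                                                      max_iter = 20L,
                                                      seed = 5))
  expect_false(identical(ft$W, src$W))
  # determinism
  ft2 <- finetune_transfer(d$Xs, d$ys, d$Xt_tr, d$yt_tr, quick_spec(10),
                           pretrain_cfg = quick_train(seed = 5),
                           finetune_cfg = train_config(lr = 0.002,
                                                       batch_size = 10L,
                                                       max_iter = 20L,
                                                       seed = 5))
  expect_identical(ft$W, ft2$W)
  expect_error(finetune_transfer(d$Xs, d$ys, d$Xt_tr[, 1:5], d$yt_tr,
                                 quick_spec(10)), "feature space")
})

test_that("when target matches source, fine-tuning beats target-only training", {
  # both groups share one distribution; pretraining on the large source
  # should help the small-target model on median over repeated splits
  deltas <- sapply(1:8, function(s) {
    d <- toy_domains(seed = s)
    ft <- finetune_transfer(d$Xs, d$ys, d$Xt_tr, d$yt_tr, quick_spec(10),
                            pretrain_cfg = quick_train(seed = s),
                            finetune_cfg = train_config(lr = 0.002,
                                                        batch_size = 10L,
                                                        max_iter = 30L,
                                                        seed = s))
    own <- mlp_train(d$Xt_tr, d$yt_tr, quick_spec(10),
                     train_config(batch_size = 4L, max_iter = 30L, seed = s))
    auroc(predict_proba(ft, d$Xt_te), d$yt_te) -
      auroc(predict_proba(own, d$Xt_te), d$yt_te)
  })
  expect_gte(median(deltas), 0)
})

test_that("the SDA classifier inherits the trained encoder and its shape", {
  d <- toy_domains(seed = 3)
  sda <- sda_pretrain(rbind(d$Xs, d$Xt_tr), quick_sda(10))
  cls <- sda_to_classifier(sda, seed = 2)
  expect_identical(cls$W[[1]], sda$encoder_W[[1]])
  expect_identical(cls$W[[2]], sda$encoder_W[[2]])
  expect_equal(dim(cls$W[[3]]), c(8, 1))  # bottleneck -> logistic output
  fit <- sda_transfer(d$Xs, d$ys, d$Xt_tr, d$yt_tr, quick_sda(10),
                      finetune_cfg = train_config(lr = 0.002,
                                                  batch_size = 10L,
                                                  max_iter = 20L, seed = 2))
  # same architecture as the pyramid classifier: input -> 16 -> 8 -> 1
  expect_equal(sapply(fit$W, ncol), c(16, 8, 1))
})

test_that("pair losses match the exhaustive double loop and hand values", {
  set.seed(7)
  for (rep in 1:5) {
    ns <- sample(3:15, 1); nt <- sample(3:15, 1); k <- 4
    Es <- matrix(rnorm(ns * k), ns, k)
    Et <- matrix(rnorm(nt * k), nt, k)
    ys <- sample(c(0, 1), ns, TRUE)
    yt <- sample(c(0, 1), nt, TRUE)
    fast <- ccsa_pair_losses(Es, Et, ys, yt, margin_m = 1.5)
    slow <- pair_losses_bruteforce(Es, Et, ys, yt, 1.5)
    expect_equal(fast$L_SA, slow$L_SA, tolerance = 1e-12)
    expect_equal(fast$L_S, slow$L_S, tolerance = 1e-12)
    expect_gte(fast$L_SA, 0)
    expect_gte(fast$L_S, 0)
  }
  # identical embeddings of a same-label pair contribute nothing
  E <- matrix(c(1, 2), 1, 2)
  expect_equal(ccsa_pair_losses(E, E, 1, 1, 0.3)$L_SA, 0)
  # different-label pair beyond the margin contributes nothing
  E2 <- matrix(c(1.5, 2), 1, 2)   # distance 0.5 > m = 0.3
  expect_equal(ccsa_pair_losses(E, E2, 1, 0, 0.3)$L_S, 0)
  # different-label pair at distance 0.1 with m = 0.3: 0.5 * 0.2^2 = 0.02
  E3 <- matrix(c(1.1, 2), 1, 2)
  expect_equal(ccsa_pair_losses(E, E3, 1, 0, 0.3)$L_S, 0.02,
               tolerance = 1e-12)
  # L_S vanishes whenever every different-label distance >= m
  far <- ccsa_pair_losses(E * 10, E2 * -10, 1, 0, 0.3)
  expect_equal(far$L_S, 0)
})

test_that("CCSA training composes its loss from independent components", {
  d <- toy_domains(seed = 4)
  Xs <- l2_normalize_rows(d$Xs)
  Xt <- l2_normalize_rows(d$Xt_tr)
  cfg <- ccsa_config(gamma = 0.4, hidden_nodes = 12L, max_iter = 15L,
                     seed = 6)
  fit <- ccsa_train(Xs, d$ys, Xt, d$yt_tr, cfg)
  # fixed mini-batch: first 10 source and first 10 target samples
  bs <- 1:10
  ev <- ccsa_eval_loss(fit, Xs[bs, ], d$ys[bs], Xt[bs, ], d$yt_tr[bs],
                       gamma = 0.4, margin_m = 0.3)
  emb_s <- ccsa_embed(fit, Xs[bs, ])
  emb_t <- ccsa_embed(fit, Xt[bs, ])
  pl <- ccsa_pair_losses(emb_s, emb_t, d$ys[bs], d$yt_tr[bs], 0.3)
  # classification term recomputed through the generic forward pass
  p <- predict_proba(fit, rbind(Xs[bs, ], Xt[bs, ]))
  ycomb <- c((d$ys[bs] + 1) / 2, (d$yt_tr[bs] + 1) / 2)
  lc <- -mean(ycomb * log(p) + (1 - ycomb) * log(1 - p))
  expect_equal(ev$lsa, pl$L_SA, tolerance = 1e-10)
  expect_equal(ev$ls, pl$L_S, tolerance = 1e-10)
  expect_equal(ev$lc, lc, tolerance = 1e-10)
  expect_equal(ev$total, 0.6 * lc + 0.4 * (pl$L_SA + pl$L_S),
               tolerance = 1e-10)
})

test_that("CCSA limiting cases behave as the loss dictates", {
  d <- toy_domains(seed = 5)
  Xs <- l2_normalize_rows(d$Xs)
  Xt <- l2_normalize_rows(d$Xt_tr)
  # gamma = 0: total logged loss equals the classification component
  f0 <- ccsa_train(Xs, d$ys, Xt, d$yt_tr,
                   ccsa_config(gamma = 0, hidden_nodes = 12L,
                               max_iter = 10L, seed = 2))
  expect_equal(f0$loss_log[, "total"], f0$loss_log[, "lc"],
               tolerance = 1e-12)
  # gamma = 1: the classification term is absent from the loss
  f1 <- ccsa_train(Xs, d$ys, Xt, d$yt_tr,
                   ccsa_config(gamma = 1, hidden_nodes = 12L,
                               max_iter = 10L, seed = 2))
  expect_equal(f1$loss_log[, "total"],
               f1$loss_log[, "lsa"] + f1$loss_log[, "ls"],
               tolerance = 1e-12)
  # determinism under a fixed seed
  f0b <- ccsa_train(Xs, d$ys, Xt, d$yt_tr,
                    ccsa_config(gamma = 0, hidden_nodes = 12L,
                                max_iter = 10L, seed = 2))
  expect_identical(f0$W, f0b$W)
  # un-normalized inputs are rejected
  expect_error(ccsa_train(d$Xs, d$ys, Xt, d$yt_tr, ccsa_config()),
               "L2-normalized")
})

test_that("under inequality and discrepancy, transfer narrows the disparity gap", {
  # scaled-down analogue of the unequal/discrepant condition: the transfer
  # scheme should beat the mixture scheme's minority performance and bring
  # G_tilde below G
  co <- generate_cohort(synthetic_config(n1 = 400, n2 = 90, n_features = 50,
                                         n_de = 6,
                                         beta_counts = c(16, 9, 9, 16),
                                         seed = 5))
  cfg <- suite_config(net = net_spec(50, hidden = c(32L, 16L)),
                      train = train_config(max_iter = 60L),
                      pretrain = train_config(max_iter = 60L),
                      finetune = train_config(lr = 0.002, batch_size = 10L,
                                              max_iter = 60L),
                      sda = sda_spec(50, hidden = c(32L, 16L, 32L),
                                     max_iter = 150L),
                      ccsa = ccsa_config(max_iter = 60L))
  res <- run_suite(co, n_runs = 3,
                   experiments = c("mixture", "independent", "transfer"),
                   config = cfg, seed = 9)
  gr <- gap_report(res)
  expect_gt(gr$medians[["Transfer"]], gr$medians[["Mixture2"]])
  expect_lt(gr$G_tilde, gr$G)
  # selection dominance: the winning AUROC is the max of the three methods
  expect_true(all(res$folds$auroc[res$folds$experiment == "Transfer"] >= 0))
})

test_that("best-of-three selection returns the maximum with fixed tie order", {
  d <- toy_domains(seed = 8)
  res <- transfer_best(d$Xs, d$ys, d$Xt_tr, d$yt_tr, d$Xt_te, d$yt_te,
                       spec = quick_spec(10),
                       pretrain_cfg = quick_train(seed = 3),
                       finetune_cfg = train_config(lr = 0.002,
                                                   batch_size = 10L,
                                                   max_iter = 20L, seed = 3),
                       sda = quick_sda(10),
                       ccsa = ccsa_config(hidden_nodes = 12L,
                                          max_iter = 20L, seed = 3))
  expect_true(res$method %in% c("finetune", "sda", "ccsa"))
  expect_equal(res$auroc, max(res$all_aurocs, na.rm = TRUE))
  expect_equal(res$auroc, unname(res$all_aurocs[res$method]))
  # tie-break on identical values keeps the fixed method order
  aurocs <- c(finetune = 0.7, sda = 0.7, ccsa = 0.7)
  expect_equal(names(aurocs)[which.max(aurocs)], "finetune")
})
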