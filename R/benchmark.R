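#' Stratified threefold split
#'
#' Assigns every sample to one of `n_folds` folds so that, within each
#' stratum, fold sizes differ by at most one. In `mixture` mode strata are
#' the joint (label, group) cells; in `independent` mode they are the label
#' classes only (callers pass one group's samples).
#'
#' @param y Label per sample.
#' @param group Group id per sample (ignored in `independent` mode).
#' @param mode `"mixture"` (stratify by label and group) or `"independent"`
#'   (label only).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `fold` (0-based fold id
#'   per sample), `strata`, `mode`.
#' @export
stratified_threefold <- function(y, group = NULL, mode = c("mixture",
                                                           "independent"),
                                 n_folds = 3L, seed = 1L) {
  mode <- match.arg(mode)
  strata <- if (mode == "mixture") {
    if (is.null(group)) stop("mixture mode requires a group vector")
    interaction(y, group, drop = TRUE)
  } else {
    factor(y)
  }
  set.seed(derive_seed(seed, 7))
  fold <- integer(length(y))
  for (s in levels(strata)) {
    idx <- which(strata == s)
    if (length(idx) < n_folds)
      warning("stratum '", s, "' has only ", length(idx),
              " samples for ", n_folds, " folds")
    fold[sample(idx)] <- rep_len(sample.int(n_folds) - 1L, length(idx))
  }
  structure(list(fold = fold, strata = strata, mode = mode,
                 n_folds = as.integer(n_folds)),
            class = "fold_plan")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the fraction of (positive, negative)
#' pairs in which the positive sample is scored higher, ties counted one
#' half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Labels in `{-1, +1}` or `{0, 1}`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC undefined: only one class present")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Configuration for the six-experiment benchmark suite
#'
#' @param net [net_spec()] used by every experiment (input size is filled in
#'   from the cohort at run time when `NULL`).
#' @param train Base [train_config()] (mixture and majority-group models;
#'   batch size 20).
#' @param minority_batch_size Batch size for the minority-group independent
#'   model; `NULL` picks 4 when the minority group is smaller than the
#'   majority and 20 otherwise.
#' @param pretrain,finetune,sda,ccsa Transfer-method configurations (see
#'   [transfer_best()]).
#' @return Object of class `suite_config`.
#' @export
suite_config <- function(net = NULL, train = train_config(),
                         minority_batch_size = NULL,
                         pretrain = train_config(),
                         finetune = train_config(lr = 0.002,
                                                 batch_size = 10L),
                         sda = NULL, ccsa = ccsa_config()) {
  structure(list(net = net, train = train,
                 minority_batch_size = minority_batch_size,
                 pretrain = pretrain, finetune = finetune, sda = sda,
                 ccsa = ccsa),
            class = "suite_config")
}

with_seed_cfg <- function(cfg, seed, batch_size = NULL) {
  cfg$seed <- as.integer(seed)
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  cfg
}

#' Run the multiethnic machine learning experiment suite
#'
#' Per run: (a) mixture learning — threefold CV stratified jointly by label
#' and group; one model per fold evaluated on the full test fold
#' (`Mixture0`) and its group-1 / group-2 subsets (`Mixture1`, `Mixture2`);
#' (b) independent learning — per-group label-stratified threefold CV with
#' one model per group per fold (`Independent1`, `Independent2`); (c)
#' transfer learning — all group-1 samples as source, group-2 split by the
#' independent-scheme folds, scored by the best of the three transfer
#' methods on the target test fold (`Transfer`). Fold AUROCs are averaged
#' into one value per experiment per run; runs use independent random
#' partitions.
#'
#' @param cohort A `cohort` (its `X` is used as-is; generated cohorts are
#'   already standardized).
#' @param n_runs Number of independent runs.
#' @param experiments Subset of `c("mixture", "independent", "transfer")`.
#' @param config A [suite_config()].
#' @param seed Master seed; per-run/fold/model seeds are derived from it.
#' @return Object of class `suite_result`: `folds` (long data frame:
#'   experiment, run, fold, auroc) and `runs` (per-run fold means, wide).
#' @export
run_suite <- function(cohort, n_runs = 20L,
                      experiments = c("mixture", "independent", "transfer"),
                      config = suite_config(), seed = 1L) {
  X <- cohort$X
  y <- cohort$y
  group <- cohort$group
  p <- ncol(X)
  spec <- if (is.null(config$net)) net_spec(p) else config$net
  sda <- if (is.null(config$sda)) sda_spec(p) else config$sda
  n1 <- sum(group == 1L)
  n2 <- sum(group == 2L)
  minority_bs <- if (is.null(config$minority_batch_size)) {
    if (n2 < n1) 4L else config$train$batch_size
  } else as.integer(config$minority_batch_size)

  exp_names <- c("Mixture0", "Mixture1", "Mixture2", "Independent1",
                 "Independent2", "Transfer")
  rows <- list()
  add <- function(experiment, run, fold, value) {
    rows[[length(rows) + 1L]] <<- data.frame(experiment = experiment,
                                             run = run, fold = fold,
                                             auroc = value)
  }
  fold_auc <- function(scores, labels, subset = NULL) {
    if (!is.null(subset)) {
      scores <- scores[subset]
      labels <- labels[subset]
    }
    tryCatch(auroc(scores, labels), error = function(e) NA_real_)
  }

  for (r in seq_len(n_runs)) {
    if ("mixture" %in% experiments) {
      plan <- stratified_threefold(y, group, "mixture",
                                   seed = derive_seed(seed, r, 1))
      for (f in 0:2) {
        tr <- plan$fold != f
        te <- !tr
        fit <- mlp_train(X[tr, , drop = FALSE], y[tr], spec,
                         with_seed_cfg(config$train,
                                       derive_seed(seed, r, 1, f)))
        sc <- predict_proba(fit, X[te, , drop = FALSE])
        add("Mixture0", r, f, fold_auc(sc, y[te]))
        add("Mixture1", r, f, fold_auc(sc, y[te], group[te] == 1L))
        add("Mixture2", r, f, fold_auc(sc, y[te], group[te] == 2L))
      }
    }
    need_indep_folds <- any(c("independent", "transfer") %in% experiments)
    if (need_indep_folds) {
      plans <- lapply(1:2, function(g)
        stratified_threefold(y[group == g], mode = "independent",
                             seed = derive_seed(seed, r, 2, g)))
    }
    if ("independent" %in% experiments) {
      for (g in 1:2) {
        idx_g <- which(group == g)
        bs <- if (g == 1L) config$train$batch_size else minority_bs
        for (f in 0:2) {
          tr <- idx_g[plans[[g]]$fold != f]
          te <- idx_g[plans[[g]]$fold == f]
          fit <- mlp_train(X[tr, , drop = FALSE], y[tr], spec,
                           with_seed_cfg(config$train,
                                         derive_seed(seed, r, 2, g, f), bs))
          sc <- predict_proba(fit, X[te, , drop = FALSE])
          add(paste0("Independent", g), r, f, fold_auc(sc, y[te]))
        }
      }
    }
    if ("transfer" %in% experiments) {
      idx1 <- which(group == 1L)
      idx2 <- which(group == 2L)
      for (f in 0:2) {
        tr <- idx2[plans[[2]]$fold != f]
        te <- idx2[plans[[2]]$fold == f]
        sd_f <- derive_seed(seed, r, 3, f)
        res <- transfer_best(
          X[idx1, , drop = FALSE], y[idx1],
          X[tr, , drop = FALSE], y[tr],
          X[te, , drop = FALSE], y[te],
          spec = spec,
          pretrain_cfg = with_seed_cfg(config$pretrain, sd_f),
          finetune_cfg = with_seed_cfg(config$finetune, sd_f),
          sda = with_seed_cfg(sda, sd_f),
          ccsa = with_seed_cfg(config$ccsa, sd_f))
        add("Transfer", r, f, res$auroc)
      }
    }
  }
  folds <- do.call(rbind, rows)
  runs <- stats::aggregate(auroc ~ experiment + run, folds, mean,
                           na.rm = TRUE)
  structure(list(folds = folds, runs = runs,
                 experiments = intersect(
                   exp_names, unique(folds$experiment)),
                 n_runs = n_runs, seed = seed),
            class = "suite_result")
}

#' Per-run AUROC values of one experiment
#'
#' @param result A `suite_result`.
#' @param experiment Experiment name (e.g. `"Mixture1"`).
#' @return Numeric vector ordered by run.
#' @export
run_values <- function(result, experiment) {
  sub <- result$runs[result$runs$experiment == experiment, ]
  sub$auroc[order(sub$run)]
}

#' Disparity gap report
#'
#' Computes the median AUROC per experiment, the per-scheme gaps
#' (`Mixture1 - Mixture2`, `Independent1 - Independent2`), the disparity
#' gap `G = mean(Mixture1, Independent1) - mean(Mixture2, Independent2)`,
#' and, when the transfer experiment is present, the reduced gap
#' `G_tilde = mean(Mixture1, Independent1) - Transfer`. Per-scheme gaps are
#' called "yes" when they exceed `threshold`.
#'
#' @param result A `suite_result` from [run_suite()], or a named numeric
#'   vector of experiment medians.
#' @param threshold Gap threshold for the yes/no call.
#' @return Object of class `gap_report`.
#' @export
gap_report <- function(result, threshold = 0.05) {
  medians <- if (inherits(result, "suite_result")) {
    stats::setNames(
      vapply(unique(result$runs$experiment),
             function(e) median(run_values(result, e), na.rm = TRUE),
             numeric(1)),
      unique(result$runs$experiment))
  } else {
    result
  }
  need <- c("Mixture1", "Mixture2", "Independent1", "Independent2")
  missing <- setdiff(need, names(medians))
  if (length(missing) > 0)
    stop("missing experiments: ", paste(missing, collapse = ", "))
  auroc_ea <- (medians[["Mixture1"]] + medians[["Independent1"]]) / 2
  auroc_aa <- (medians[["Mixture2"]] + medians[["Independent2"]]) / 2
  g <- auroc_ea - auroc_aa
  g_tilde <- if ("Transfer" %in% names(medians))
    auroc_ea - medians[["Transfer"]] else NA_real_
  mixture_gap <- medians[["Mixture1"]] - medians[["Mixture2"]]
  independent_gap <- medians[["Independent1"]] - medians[["Independent2"]]
  structure(list(medians = medians, auroc_ea = auroc_ea,
                 auroc_aa = auroc_aa, G = g, G_tilde = g_tilde,
                 mixture_gap = mixture_gap,
                 independent_gap = independent_gap,
                 mixture_gap_call = unname(mixture_gap > threshold),
                 independent_gap_call = unname(independent_gap > threshold),
                 threshold = threshold),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat("Disparity gap report (threshold ", x$threshold, ")\n", sep = "")
  cat("  medians:", paste(sprintf("%s=%.3f", names(x$medians), x$medians),
                          collapse = "  "), "\n")
  cat(sprintf("  mixture gap     %.3f  -> gap %s\n", x$mixture_gap,
              ifelse(x$mixture_gap_call, "yes", "no")))
  cat(sprintf("  independent gap %.3f  -> gap %s\n", x$independent_gap,
              ifelse(x$independent_gap_call, "yes", "no")))
  cat(sprintf("  G = %.3f", x$G))
  if (!is.na(x$G_tilde)) cat(sprintf("   G_tilde = %.3f", x$G_tilde))
  cat("\n")
  invisible(x)
}
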