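#' Write a cohort to a directory
#'
#' Emits the package's plain-text cohort dialect: `features.tsv` (samples x
#' features, header row of feature ids, first column `sample_id`),
#' `labels.tsv` (`sample_id`, `label`, `group`), and `truth.json` (ground
#' truth and generator configuration, when present).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- data.frame(sample_id = cohort$sample_ids, cohort$X,
                     check.names = FALSE)
  colnames(feat) <- c("sample_id", cohort$feature_ids)
  write.table(feat, file.path(dir, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lab <- data.frame(sample_id = cohort$sample_ids, label = cohort$y,
                    group = cohort$group)
  write.table(lab, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(cohort$truth)) {
    truth <- cohort$truth
    truth$config <- unclass(truth$config)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load a cohort from a directory
#'
#' Reads the `features.tsv` / `labels.tsv` dialect written by
#' [write_cohort()], validating sample-id consistency, numeric features, and
#' label/group codings.
#'
#' @param dir Directory containing `features.tsv` and `labels.tsv`.
#' @return A `cohort`.
#' @export
load_cohort <- function(dir) {
  fpath <- file.path(dir, "features.tsv")
  lpath <- file.path(dir, "labels.tsv")
  if (!file.exists(fpath) || !file.exists(lpath))
    stop("cohort directory must contain features.tsv and labels.tsv: ", dir)
  feat <- read.delim(fpath, check.names = FALSE)
  lab <- read.delim(lpath)
  if (anyDuplicated(feat$sample_id))
    stop("duplicated sample id in features.tsv: ",
         feat$sample_id[duplicated(feat$sample_id)][1])
  if (!identical(as.character(feat$sample_id), as.character(lab$sample_id)))
    stop("sample ids in features.tsv and labels.tsv do not match")
  X <- as.matrix(feat[, -1, drop = FALSE])
  if (!is.numeric(X)) {
    bad <- which(!vapply(feat[-1], is.numeric, logical(1)))[1]
    stop("non-numeric feature column: ", colnames(feat)[-1][bad])
  }
  if (!all(lab$label %in% c(-1, 1))) {
    bad <- lab$label[!lab$label %in% c(-1, 1)][1]
    stop("unknown label value: ", bad)
  }
  if (!all(lab$group %in% c(1, 2))) {
    bad <- lab$group[!lab$group %in% c(1, 2)][1]
    stop("unknown group value: ", bad)
  }
  rownames(X) <- as.character(feat$sample_id)
  structure(list(X = X, y = as.integer(lab$label),
                 group = as.integer(lab$group),
                 feature_ids = colnames(X),
                 sample_ids = as.character(feat$sample_id), truth = NULL),
            class = "cohort")
}

#' Write a gap report as JSON
#'
#' @param report A `gap_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path) {
  out <- list(medians = as.list(report$medians),
              auroc_ea = report$auroc_ea, auroc_aa = report$auroc_aa,
              G = report$G, G_tilde = report$G_tilde,
              mixture_gap = report$mixture_gap,
              independent_gap = report$independent_gap,
              mixture_gap_call = report$mixture_gap_call,
              independent_gap_call = report$independent_gap_call,
              threshold = report$threshold)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-fold suite results as TSV
#'
#' @param result A `suite_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_suite_result <- function(result, path) {
  write.table(result$folds, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
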