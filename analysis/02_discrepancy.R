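#!/usr/bin/env Rscript
# Quantify the marginal and conditional distribution discrepancy that the
# generator planted in each cohort: the fraction of features that a
# permutation t-test calls differentially expressed between the groups, and
# the Pearson correlation between the per-group multivariate logistic
# regression coefficients. Reads the cohorts written by 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(equibench))

rows <- list()
for (d in 1:4) {
  dir <- file.path("scratch", "cohorts", paste0("synthetic_data_", d))
  cohort <- load_cohort(dir)
  rep <- discrepancy_report(cohort, n_permutations = 1000,
                            seed = derive_seed(2, d))
  rows[[d]] <- data.frame(dataset = d, de_fraction = rep$de_fraction,
                          beta_pearson_r = rep$pearson_r)
  message(sprintf(
    "synthetic data %d: DE fraction %.3f, beta correlation r = %.3f",
    d, rep$de_fraction, rep$pearson_r))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/discrepancy.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
# Expected pattern: datasets 1 and 3 show a DE fraction well above the 0.05
# nominal level and a depressed beta correlation; datasets 2 and 4 sit at
# the nominal level with strongly correlated coefficients.
print(tab)
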