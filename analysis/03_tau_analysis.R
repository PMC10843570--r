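#!/usr/bin/env Rscript
# Characterize longitudinal tau change across NFT stage regions as a function
# of A+ chronicity: cross-sectional correlations (age / amyloid burden /
# chronicity vs stage SUVR), annualized % change by chronicity bin, and
# Cohen's d effect sizes between baseline and follow-up scans.

suppressPackageStartupMessages({
  library(amychron)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--results-dir", dest = "dir", default = "results")
)))

cohort <- read_cohort(file.path(opts$dir, "cohort.csv"))
estimates <- utils::read.csv(file.path(opts$dir, "estimates.csv"))
res <- run_tau_analysis(cohort, estimates)

utils::write.csv(res$correlations, file.path(opts$dir, "correlations.csv"),
                 row.names = FALSE)
utils::write.csv(res$tau_change, file.path(opts$dir, "tau_change.csv"),
                 row.names = FALSE)
utils::write.csv(res$bin_summary, file.path(opts$dir, "bin_summary.csv"),
                 row.names = FALSE)

cat("Pearson r (stage SUVR vs predictor), baseline tau scans:\n")
print(reshape(res$correlations[, c("predictor", "stage", "r")],
              idvar = "predictor", timevar = "stage", direction = "wide"),
      digits = 2)

cat("\nannualized % tau change, mean by chronicity bin x stage:\n")
pct <- reshape(res$bin_summary[, c("chronicity_bin", "stage",
                                   "mean_pct_rate")],
               idvar = "chronicity_bin", timevar = "stage",
               direction = "wide")
print(pct, digits = 2)

cat("\nCohen's d (follow-up vs baseline) by chronicity bin x stage:\n")
es <- reshape(res$bin_summary[, c("chronicity_bin", "stage", "cohens_d")],
              idvar = "chronicity_bin", timevar = "stage",
              direction = "wide")
print(es, digits = 2)

n_by_bin <- unique(res$bin_summary[, c("chronicity_bin", "n",
                                       "mean_burden_cl")])
cat("\nsubjects and mean baseline burden per bin:\n")
print(n_by_bin, digits = 3, row.names = FALSE)
cat(sprintf("\nwrote correlations.csv, tau_change.csv, bin_summary.csv under %s\n",
            opts$dir))
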