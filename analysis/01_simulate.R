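#!/usr/bin/env Rscript
# Simulate the synthetic longitudinal amyloid/tau cohort at the study-default
# design (177 subjects; amyloid scan counts 58/64/15/30/10 for 1..5 scans;
# 75 one-tau and 92 two-tau subjects; visits every 2-3 years) and write the
# visit table under results/.

suppressPackageStartupMessages({
  library(amychron)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n-subjects", dest = "n_subjects", type = "integer",
              default = NULL),
  make_option("--out-dir", dest = "out_dir", default = "results")
)))

cfg <- if (is.null(opts$n_subjects)) cohort_config(seed = opts$seed) else {
  # free-form cohort sizes keep the default scan-count mix proportionally
  n <- opts$n_subjects
  mix <- c(58, 64, 15, 30, 10) / 177
  scd <- diff(c(0, round(cumsum(mix * n))))
  names(scd) <- 1:5
  tsd <- c(`1` = round(0.42 * n), `2` = round(0.52 * n))
  cohort_config(n_subjects = n, scan_count_distribution = scd,
                tau_subset_distribution = tsd, seed = opts$seed)
}

cohort <- generate_cohort(cfg)
dir.create(opts$out_dir, recursive = TRUE, showWarnings = FALSE)
write_cohort(cohort, file.path(opts$out_dir, "cohort.csv"), config = cfg)

amy <- cohort[cohort$modality == "amyloid", ]
scan_tab <- table(table(amy$subject_id))
cat(sprintf("cohort: %d subjects, %d amyloid scans, %d tau scans\n",
            length(unique(cohort$subject_id)), nrow(amy),
            sum(cohort$modality == "tau")))
cat(sprintf("amyloid scans per subject: %s\n",
            paste(sprintf("%s:%d", names(scan_tab), scan_tab), collapse = " ")))
cat(sprintf("scan age %.1f (%.1f) years; %d/%d scans A+\n",
            mean(amy$age), sd(amy$age), sum(is_apositive(amy$abl)), nrow(amy)))
cat(sprintf("wrote %s\n", file.path(opts$out_dir, "cohort.csv")))
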