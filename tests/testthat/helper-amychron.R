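# shared fixtures, built once per test run and cached

.amychron_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .amychron_cache)) {
    assign(key, force(expr), envir = .amychron_cache)
  }
  get(key, envir = .amychron_cache)
}

# a small, fast cohort: 30 subjects, all with >= 2 amyloid scans
small_config <- function(seed = 1L, ...) {
  cohort_config(n_subjects = 30L,
                scan_count_distribution = c(`2` = 20L, `3` = 10L),
                tau_subset_distribution = c(`1` = 5L, `2` = 15L),
                seed = seed, ...)
}

default_cohort <- function() {
  cached("default_cohort", generate_cohort(cohort_config()))
}

# noise-free amyloid cohort (tiny tau noise keeps SUVR strictly positive
# without affecting amyloid-side checks)
noise_free_fit <- function() {
  cached("noise_free_fit", {
    cohort <- generate_cohort(cohort_config(noise_sd_abl = 0))
    list(cohort = cohort, fit = estimate_cohort_chronicity(cohort))
  })
}

onset_truth <- function(cohort) {
  unique(cohort[, c("subject_id", "true_onset_age")])
}

# full pipeline across seeds 1..20 at study-default settings; returns one
# row per seed with the pooled onset-error summaries and early-bin tau
# contrasts used by the recovery and emergence checks
multi_seed_runs <- function() {
  cached("multi_seed_runs", {
    lapply(1:20, function(s) {
      cohort <- generate_cohort(cohort_config(seed = s))
      fit <- estimate_cohort_chronicity(cohort)
      m <- merge(fit$estimates, onset_truth(cohort))
      res <- run_tau_analysis(cohort, fit$estimates)
      bs <- res$bin_summary
      co <- res$correlations
      pct <- function(bin, stage) {
        bs$mean_pct_rate[bs$chronicity_bin == bin & bs$stage == stage]
      }
      early_gain <- vapply(c("I", "II", "III"), function(st) {
        isTRUE(pct("0-2.5", st) > pct("<0", st)) &&
          isTRUE(pct("2.5-5", st) > pct("<0", st))
      }, logical(1))
      list(onset_abs_err = abs(m$estimated_onset_age - m$true_onset_age),
           truncated = m$truncated,
           early_gain = all(early_gain),
           stage1_chron_beats_age =
             co$r[co$predictor == "chronicity" & co$stage == "I"] >
             co$r[co$predictor == "age" & co$stage == "I"])
    })
  })
}

# independent fixed-step RK4 integrator for the burden ODE (test oracle)
rk4_burden <- function(config, t_end, h = 0.001, a0 = 13.3) {
  f <- function(a) amyloid_rate_law(a, config)
  n <- round(abs(t_end) / h)
  s <- sign(t_end) * h
  a <- a0
  for (i in seq_len(n)) {
    k1 <- f(a)
    k2 <- f(a + s * k1 / 2)
    k3 <- f(a + s * k2 / 2)
    k4 <- f(a + s * k3)
    a <- a + s * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  a
}

logistic_solution <- function(t, rho = 0.1, K = 100, a0 = 13.3) {
  K / (1 + ((K - a0) / a0) * exp(-rho * t))
}

logistic_field <- function(rho = 0.1, K = 100) {
  g <- seq(0.01, 110, by = 0.05)
  rate_field(g, rho * g * (1 - g / K))
}
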