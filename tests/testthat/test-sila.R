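two_scan_visits <- function(id, ages, abl) {
  data.frame(subject_id = id, age = ages, modality = "amyloid", abl = abl,
             cl = abl_to_cl(abl), nft1 = NA_real_, nft2 = NA_real_,
             nft3 = NA_real_, nft4 = NA_real_, nft5 = NA_real_,
             nft6 = NA_real_)
}

test_that("rate samples are adjacent-pair finite differences at midpoint burden", {
  v <- two_scan_visits("A", c(40, 42), c(10, 14))
  s <- compute_rate_samples(v)
  expect_equal(s$burden, 12)
  expect_equal(s$rate, 2.0)
  # three equally spaced scans on a linear trajectory: identical rates
  v3 <- two_scan_visits("B", c(40, 42, 44), c(10, 13, 16))
  s3 <- compute_rate_samples(v3)
  expect_equal(nrow(s3), 2L)
  expect_equal(s3$rate, c(1.5, 1.5))
  # subject-level OLS strategy recovers the same slope on linear data
  s_ols <- compute_rate_samples(v3, method = "subject_slope")
  expect_equal(nrow(s_ols), 1L)
  expect_equal(s_ols$rate, 1.5, tolerance = 1e-12)
  expect_equal(s_ols$burden, 13)
})

test_that("rate sampling requires a multi-scan subject and distinct ages", {
  single <- two_scan_visits("A", 40, 10)
  expect_error(compute_rate_samples(single), ">= 2 amyloid scans")
  dup <- two_scan_visits("A", c(40, 40), c(10, 11))
  expect_error(compute_rate_samples(dup), "distinct")
})

test_that("rate field smoothing averages within windows and interpolates gaps", {
  s <- data.frame(subject_id = "A", burden = c(8, 12, 18, 25),
                  rate = c(1.4, 1.4, 1.4, 1.4), weight = 2L)
  f <- fit_rate_field(s, grid = seq(8, 25, by = 1), window = 5)
  covered <- f$n_per_window > 0
  expect_true(all(abs(f$mean_rate[covered] - 1.4) < 1e-12))
  expect_true(all(f$sd_rate[covered] < 1e-12))
  # empty window at burden 20 between samples at 10 and 30: linear interp
  s2 <- data.frame(subject_id = "A", burden = c(10, 30), rate = c(1, 3),
                   weight = 2L)
  f2 <- fit_rate_field(s2, grid = c(10, 20, 30), window = 5)
  expect_equal(f2$n_per_window, c(1L, 0L, 1L))
  expect_equal(f2$mean_rate[2], 2)
  # all windows empty is an error
  expect_error(fit_rate_field(s2, grid = c(100, 101), window = 0.5), "empty")
})

test_that("noise-free rate field recovers the generating sigmoid law", {
  nf <- noise_free_fit()
  field <- nf$fit$field
  truth <- amyloid_rate_law(field$grid_burden, cohort_config())
  ok <- field$n_per_window >= 10
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(field$mean_rate[ok] - truth[ok])), 0.1)
})

test_that("constant rate field integrates to a straight line spanning 50 years", {
  f <- rate_field(c(0, 100), c(1.4, 1.4))
  curve <- integrate_trajectory(f)
  expect_equal(max(curve$chronicity), 50)
  expect_equal(min(curve$chronicity), -50)
  expect_equal(curve$abl, 13.3 + 1.4 * curve$chronicity, tolerance = 1e-9)
  expect_error(integrate_trajectory(rate_field(c(0, 100), c(-1, -1))),
               "degenerate")
})

test_that("Euler integration tracks the analytic logistic solution", {
  fld <- logistic_field()
  curve <- integrate_trajectory(fld)
  err <- max(abs(curve$abl - logistic_solution(curve$chronicity)))
  # forward Euler at 0.25-yr steps: lag peaks mid-rise; measured 0.242
  expect_lt(err, 0.25)
  # first-order convergence: halving the step roughly halves the error
  curve2 <- integrate_trajectory(fld, step = 0.125, max_iter = 400L)
  err2 <- max(abs(curve2$abl - logistic_solution(curve2$chronicity)))
  expect_lt(err2, err)
  expect_gt(err / err2, 1.7)
  expect_lt(err / err2, 2.3)
})

test_that("curve is monotone, anchored, and invertible at the anchor", {
  nf <- noise_free_fit()
  curve <- nf$fit$curve
  expect_true(all(diff(curve$abl) > 0))
  expect_equal(curve$abl[curve$chronicity == 0], 13.3, tolerance = 1e-9)
  inv <- chronicity_at_burden(curve, 13.3)
  expect_equal(inv$chronicity, 0, tolerance = 1e-9)
  expect_false(inv$truncated_low || inv$truncated_high)
})

test_that("chronicity estimation implements the single- and multi-scan cases", {
  f <- rate_field(c(-10, 100), c(1, 1)) # unit rate: chronicity = abl - 13.3
  curve <- integrate_trajectory(f)
  # single scan exactly at the cutoff
  est <- estimate_chronicity(two_scan_visits("A", 45, 13.3), curve)
  expect_equal(est$chronicity_at_reference, 0, tolerance = 1e-9)
  expect_equal(est$estimated_onset_age, 45, tolerance = 1e-9)
  expect_equal(est$method, "inverted_single_scan")
  # single scan 5 burden units above the cutoff -> chronicity 5, onset 40
  est2 <- estimate_chronicity(two_scan_visits("A", 45, 18.3), curve)
  expect_equal(est2$chronicity_at_reference, 5, tolerance = 1e-9)
  expect_equal(est2$estimated_onset_age, 40, tolerance = 1e-9)
  # multi-scan with an A+ scan: first A+ scan is the reference
  v <- two_scan_visits("A", c(40, 43, 46), c(9, 14.3, 19))
  est3 <- estimate_chronicity(v, curve)
  expect_equal(est3$method, "aligned_first_apositive")
  expect_equal(est3$reference_age, 43)
  expect_equal(est3$chronicity_at_reference, 1, tolerance = 1e-9)
  # multi-scan never A+: most recent scan is the reference
  v4 <- two_scan_visits("A", c(40, 43), c(6, 9))
  est4 <- estimate_chronicity(v4, curve)
  expect_equal(est4$method, "aligned_most_recent_subthreshold")
  expect_equal(est4$reference_age, 43)
  expect_lt(est4$chronicity_at_reference, 0)
  # out-of-range burdens are truncated and flagged
  lo <- estimate_chronicity(two_scan_visits("A", 45, min(curve$abl) - 5), curve)
  expect_true(lo$truncated)
  expect_equal(lo$method, "truncated_below_range")
  expect_equal(lo$chronicity_at_reference, min(curve$chronicity))
  hi <- estimate_chronicity(two_scan_visits("A", 45, max(curve$abl) + 5), curve)
  expect_true(hi$truncated)
  expect_equal(hi$chronicity_at_reference, max(curve$chronicity))
  expect_error(estimate_chronicity(two_scan_visits("A", 45, 20)[0, ], curve),
               "no amyloid")
})

test_that("onset age is exactly reference age minus chronicity", {
  fit <- noise_free_fit()$fit
  est <- fit$estimates
  expect_equal(est$estimated_onset_age,
               est$reference_age - est$chronicity_at_reference)
})

test_that("noise-free cohort recovery: estimated onset within 1 year of truth", {
  nf <- noise_free_fit()
  m <- merge(nf$fit$estimates, onset_truth(nf$cohort))
  m <- m[!m$truncated, ]
  expect_gt(nrow(m), 150)
  expect_lt(max(abs(m$estimated_onset_age - m$true_onset_age)), 1)
})

test_that("an all-subthreshold cohort yields non-positive chronicities", {
  set.seed(21)
  ids <- sprintf("P%02d", 1:6)
  v <- do.call(rbind, lapply(seq_along(ids), function(i) {
    a0 <- 35 + i
    two_scan_visits(ids[i], c(a0, a0 + 2.5), c(4 + i, 5.2 + i))
  }))
  fit <- estimate_cohort_chronicity(v)
  expect_true(all(fit$estimates$method %in%
                    c("aligned_most_recent_subthreshold",
                      "truncated_below_range")))
  expect_true(all(fit$estimates$chronicity_at_reference <= 0))
})

test_that("cohort estimation is invariant to input row order", {
  cohort <- generate_cohort(small_config(seed = 9))
  fit1 <- estimate_cohort_chronicity(cohort)
  set.seed(1)
  fit2 <- estimate_cohort_chronicity(cohort[sample(nrow(cohort)), ])
  expect_equal(fit1$estimates, fit2$estimates)
  expect_equal(fit1$curve$abl, fit2$curve$abl)
})

test_that("stage errors are annotated with the failing stage", {
  single_only <- two_scan_visits("A", 40, 10)
  expect_error(estimate_cohort_chronicity(single_only), "rate_samples")
})

test_that("rigid alignment: chronicity offsets equal age offsets across scans", {
  cohort <- generate_cohort(small_config(seed = 4))
  fit <- estimate_cohort_chronicity(cohort)
  tau_res <- run_tau_analysis(cohort, fit$estimates)
  rec <- tau_res$tau_change
  # for each longitudinal subject the baseline-tau chronicity must differ from
  # the reference chronicity by exactly the age offset
  est <- fit$estimates
  for (id in unique(rec$subject_id)[1:5]) {
    d <- cohort[cohort$subject_id == id & cohort$modality == "tau", ]
    e <- est[est$subject_id == id, ]
    r <- rec[rec$subject_id == id & rec$stage == "I", ]
    expect_equal(r$chronicity_baseline - e$chronicity_at_reference,
                 min(d$age) - e$reference_age, tolerance = 1e-12)
  }
})
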