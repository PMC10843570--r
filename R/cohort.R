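#' Configuration for the synthetic longitudinal PET cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. The defaults
#' emulate a 177-person adult Down-syndrome sample: scan counts 58/64/15/30/10
#' for 1..5 amyloid scans, visits every 2-3 years, cohort ages around
#' 39 +/- 8.5 years, A+ onset ages spanning roughly 30-60 years, an
#' accumulation rate that rises with burden and plateaus at 3.73 amyloid-load
#' units/yr (~8.45 CL/yr), and stage-ordered tau onset lags after A+.
#'
#' @param n_subjects Number of subjects.
#' @param onset_age_mean,onset_age_sd Gaussian parameters (years) of the true
#'   A+ onset age, truncated to \[25, 70\].
#' @param pre_onset_rate Amyloid accumulation rate (load units/yr) far below
#'   the cutoff; small positive drift.
#' @param rate_max Plateau of the accumulation rate (load units/yr).
#' @param rate_midpoint Burden (load units) at half-maximal rate.
#' @param rate_slope Sigmoid width (load units) of the rate law.
#' @param noise_sd_abl Measurement noise SD on amyloid load.
#' @param visit_interval_range Two-vector, uniform range (years) of
#'   inter-visit gaps.
#' @param scan_count_distribution Named integer vector mapping amyloid scan
#'   count (1..5) to the number of subjects with that count; must sum to
#'   `n_subjects`.
#' @param tau_subset_distribution Named integer vector mapping tau scan count
#'   (1..2) to subject counts; the remainder of the cohort has no tau scans.
#' @param baseline_age_mean,baseline_age_sd Gaussian parameters (years) of the
#'   first-visit age, truncated to \[25, 70\]; chosen so the all-scan age
#'   distribution approximates 39.2 +/- 8.5 years.
#' @param tau_base Length-6 baseline SUVR per NFT stage (I-VI).
#' @param tau_lag Length-6 onset lag (years after A+) per stage,
#'   non-decreasing I to VI (Braak ordering).
#' @param tau_slope Length-6 post-lag accumulation slope (SUVR/yr),
#'   non-increasing I to VI so earlier stages rise first and faster.
#' @param noise_sd_suvr Measurement noise SD on stage SUVRs.
#' @param seed Integer RNG seed; the whole table is deterministic given the
#'   config.
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 4,
#'                      scan_count_distribution = c(`1` = 2, `2` = 2),
#'                      tau_subset_distribution = c(`1` = 1, `2` = 1))
cohort_config <- function(n_subjects = 177L,
                          onset_age_mean = 41,
                          onset_age_sd = 7,
                          pre_onset_rate = 0.2,
                          rate_max = 3.73,
                          rate_midpoint = 30,
                          rate_slope = 8,
                          noise_sd_abl = 1.5,
                          visit_interval_range = c(2, 3),
                          scan_count_distribution = c(`1` = 58L, `2` = 64L,
                                                      `3` = 15L, `4` = 30L,
                                                      `5` = 10L),
                          tau_subset_distribution = c(`1` = 75L, `2` = 92L),
                          baseline_age_mean = 36,
                          baseline_age_sd = 8.5,
                          tau_base = c(1.20, 1.25, 1.15, 1.10, 1.05, 1.00),
                          tau_lag = c(0, 0, 1, 3, 4, 5),
                          tau_slope = c(0.040, 0.035, 0.030,
                                        0.025, 0.022, 0.020),
                          noise_sd_suvr = 0.05,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              onset_age_mean = onset_age_mean, onset_age_sd = onset_age_sd,
              pre_onset_rate = pre_onset_rate, rate_max = rate_max,
              rate_midpoint = rate_midpoint, rate_slope = rate_slope,
              noise_sd_abl = noise_sd_abl,
              visit_interval_range = visit_interval_range,
              scan_count_distribution = scan_count_distribution,
              tau_subset_distribution = tau_subset_distribution,
              baseline_age_mean = baseline_age_mean,
              baseline_age_sd = baseline_age_sd,
              tau_base = tau_base, tau_lag = tau_lag, tau_slope = tau_slope,
              noise_sd_suvr = noise_sd_suvr, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  scd <- cfg$scan_count_distribution
  if (is.null(names(scd)) || any(is.na(suppressWarnings(as.integer(names(scd)))))) {
    stop("scan_count_distribution must be named by scan count", call. = FALSE)
  }
  if (sum(scd) != cfg$n_subjects) {
    stop(sprintf("scan_count_distribution sums to %d but n_subjects is %d",
                 sum(scd), cfg$n_subjects), call. = FALSE)
  }
  tsd <- cfg$tau_subset_distribution
  if (sum(tsd) > cfg$n_subjects) {
    stop("tau_subset_distribution counts exceed n_subjects", call. = FALSE)
  }
  for (nm in c("pre_onset_rate", "rate_max", "rate_midpoint", "rate_slope",
               "onset_age_sd", "baseline_age_sd")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be strictly positive", call. = FALSE)
  }
  # noise SDs may be zero (noise-free latent runs), never negative
  if (cfg$noise_sd_abl < 0 || cfg$noise_sd_suvr < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  vr <- cfg$visit_interval_range
  if (length(vr) != 2L || vr[1] <= 0 || vr[2] < vr[1]) {
    stop("visit_interval_range must be an increasing positive pair",
         call. = FALSE)
  }
  for (nm in c("tau_base", "tau_lag", "tau_slope")) {
    if (length(cfg[[nm]]) != 6L) stop(nm, " must have length 6", call. = FALSE)
  }
  if (any(cfg$tau_base <= 0)) stop("tau_base must be positive", call. = FALSE)
  if (is.unsorted(cfg$tau_lag)) {
    stop("tau_lag must be non-decreasing across stages I-VI", call. = FALSE)
  }
  cfg
}

#' Amyloid accumulation rate as a function of burden
#'
#' The generative rate law: a sigmoid in burden rising from `pre_onset_rate`
#' to `rate_max`, with midpoint `rate_midpoint` and width `rate_slope`. Rate
#' plateaus at high burden while burden itself never plateaus.
#'
#' @param abl Amyloid-load value(s).
#' @param config A [cohort_config()].
#' @return Accumulation rate(s) in load units per year.
#' @export
amyloid_rate_law <- function(abl, config) {
  config$pre_onset_rate + (config$rate_max - config$pre_onset_rate) *
    stats::plogis((abl - config$rate_midpoint) / config$rate_slope)
}

# Solve the latent burden ODE dA/dt = rate_law(A) in both time directions from
# the anchor (t = 0 at the A+ cutoff) and return an interpolating function of
# time-since-onset. The ODE is autonomous, so every subject's latent
# trajectory is a time shift of this single solution.
latent_burden_fun <- function(config, span = 60, grid_step = 0.05) {
  anchor <- cl_constants()$cutoff_abl
  f_fwd <- function(t, y, parms) list(amyloid_rate_law(y, config))
  f_bwd <- function(t, y, parms) list(-amyloid_rate_law(y, config))
  tt <- seq(0, span, by = grid_step)
  fwd <- deSolve::ode(y = anchor, times = tt, func = f_fwd, parms = NULL)
  bwd <- deSolve::ode(y = anchor, times = tt, func = f_bwd, parms = NULL)
  t_all <- c(-rev(tt[-1]), tt)
  a_all <- c(rev(bwd[-1, 2]), fwd[, 2])
  stats::approxfun(t_all, a_all, rule = 2)
}

#' Noise-free latent amyloid trajectory for one subject
#'
#' Integrates the burden ODE `dA/dt = amyloid_rate_law(A)` and time-shifts the
#' solution so the latent curve crosses the A+ cutoff (13.3) exactly at
#' `onset_age`. Measurement noise is *not* added here.
#'
#' @param config A [cohort_config()].
#' @param onset_age True A+ onset age in years.
#' @param eval_ages Strictly increasing ages at which to evaluate.
#' @return Latent amyloid-load values at `eval_ages`, strictly increasing.
#' @export
#' @examples
#' cfg <- cohort_config()
#' simulate_amyloid_trajectory(cfg, onset_age = 45, eval_ages = 45) # 13.3
simulate_amyloid_trajectory <- function(config, onset_age, eval_ages) {
  validate_cohort_config(config)
  check_finite(eval_ages, "eval_ages")
  if (length(eval_ages) > 1L && any(diff(eval_ages) <= 0)) {
    stop("eval_ages must be strictly increasing", call. = FALSE)
  }
  rel <- eval_ages - onset_age
  span <- max(60, ceiling(max(abs(rel))) + 1)
  latent_burden_fun(config, span = span)(rel)
}

#' Noise-free NFT-stage tau profile at a given chronicity
#'
#' Hinge-linear model per stage: SUVR stays at `tau_base[k]` until chronicity
#' exceeds the stage lag `tau_lag[k]`, then rises linearly at `tau_slope[k]`.
#' Encodes the Braak-like spatiotemporal ordering: earlier stages have shorter
#' lags and steeper slopes.
#'
#' @param chronicity A+ chronicity value(s) in years (may be negative).
#' @param config A [cohort_config()].
#' @return A matrix with `length(chronicity)` rows and 6 stage columns
#'   (`nft1`..`nft6`).
#' @export
simulate_tau_profile <- function(chronicity, config) {
  validate_cohort_config(config)
  out <- vapply(1:6, function(k) {
    config$tau_base[k] +
      config$tau_slope[k] * pmax(0, chronicity - config$tau_lag[k])
  }, numeric(length(chronicity)))
  out <- matrix(out, nrow = length(chronicity), ncol = 6L)
  colnames(out) <- paste0("nft", 1:6)
  out
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Generate a synthetic longitudinal amyloid/tau visit table
#'
#' Draws a full cohort according to `config`: amyloid scan counts match
#' `scan_count_distribution` exactly, inter-visit gaps are uniform on
#' `visit_interval_range`, onset ages are truncated-Gaussian on \[25, 70\],
#' latent amyloid follows the burden ODE anchored at the cutoff at onset, and
#' tau scans are co-scheduled with a subset of amyloid visits (two-tau
#' subjects use their first and last amyloid visit; one-tau subjects their
#' first). Gaussian measurement noise is added to amyloid load and stage
#' SUVRs. Fully deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A data.frame with one row per scan and columns `subject_id`, `age`,
#'   `modality` (`"amyloid"` or `"tau"`), `abl`, `cl`, `nft1`..`nft6`, and the
#'   synthetic ground truth `true_onset_age`. Amyloid columns are `NA` on tau
#'   rows and vice versa.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 5,
#'   scan_count_distribution = c(`2` = 5), tau_subset_distribution = c(`2` = 3)))
#' table(cohort$modality)
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%03d", seq_len(n))

  scd <- config$scan_count_distribution
  counts <- rep(as.integer(names(scd)), times = scd)
  counts <- if (n > 1L) sample(counts) else counts

  onset <- rtruncnorm1(n, config$onset_age_mean, config$onset_age_sd, 25, 70)
  base_age <- rtruncnorm1(n, config$baseline_age_mean, config$baseline_age_sd,
                          25, 70)

  ages <- lapply(seq_len(n), function(i) {
    k <- counts[i]
    gaps <- if (k > 1L) stats::runif(k - 1L, config$visit_interval_range[1],
                                     config$visit_interval_range[2]) else numeric(0)
    base_age[i] + c(0, cumsum(gaps))
  })

  # tau scan counts: two-tau subjects must have >= 2 amyloid visits to
  # co-schedule with; assign among multi-scan subjects first
  tsd <- config$tau_subset_distribution
  n2 <- if ("2" %in% names(tsd)) as.integer(tsd[["2"]]) else 0L
  n1 <- if ("1" %in% names(tsd)) as.integer(tsd[["1"]]) else 0L
  multi <- which(counts >= 2L)
  if (length(multi) < n2) {
    stop("not enough multi-scan subjects to host two tau scans", call. = FALSE)
  }
  two_tau <- if (n2 > 0L) sample(multi, n2) else integer(0)
  rest <- setdiff(seq_len(n), two_tau)
  one_tau <- if (n1 > 0L) sample(rest, n1) else integer(0)

  latent <- latent_burden_fun(config)

  rows <- lapply(seq_len(n), function(i) {
    aa <- ages[[i]]
    lat <- latent(aa - onset[i])
    abl <- lat + stats::rnorm(length(aa), 0, config$noise_sd_abl)
    amy <- data.frame(subject_id = ids[i], age = aa, modality = "amyloid",
                      abl = abl, cl = abl_to_cl(abl),
                      nft1 = NA_real_, nft2 = NA_real_, nft3 = NA_real_,
                      nft4 = NA_real_, nft5 = NA_real_, nft6 = NA_real_,
                      true_onset_age = onset[i])
    tau_ages <- if (i %in% two_tau) aa[c(1L, length(aa))] else
      if (i %in% one_tau) aa[1L] else numeric(0)
    if (length(tau_ages) == 0L) return(amy)
    suvr <- simulate_tau_profile(tau_ages - onset[i], config) +
      matrix(stats::rnorm(length(tau_ages) * 6L, 0, config$noise_sd_suvr),
             ncol = 6L)
    tau <- data.frame(subject_id = ids[i], age = tau_ages, modality = "tau",
                      abl = NA_real_, cl = NA_real_,
                      nft1 = suvr[, 1], nft2 = suvr[, 2], nft3 = suvr[, 3],
                      nft4 = suvr[, 4], nft5 = suvr[, 5], nft6 = suvr[, 6],
                      true_onset_age = onset[i])
    rbind(amy, tau)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$age, out$modality), ]
  rownames(out) <- NULL
  out
}

cohort_columns <- function() {
  c("subject_id", "age", "modality", "abl", "cl",
    paste0("nft", 1:6), "true_onset_age")
}

#' Validate a cohort visit table
#'
#' Checks the long-format scan schema: required columns present, positive
#' ages, known modalities, amyloid burden present exactly on amyloid rows,
#' stage SUVRs present and positive exactly on tau rows, and strictly
#' increasing amyloid visit ages within each subject. Errors name the
#' offending column or subject.
#'
#' @param visits A data.frame in the cohort layout (see [generate_cohort()]).
#' @return The validated table, invisibly usable downstream.
#' @export
validate_cohort <- function(visits) {
  need <- setdiff(cohort_columns(), "true_onset_age")
  miss <- setdiff(need, names(visits))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(visits$modality %in% c("amyloid", "tau"))) {
    stop("column `modality` must be 'amyloid' or 'tau'", call. = FALSE)
  }
  if (any(!is.finite(visits$age)) || any(visits$age <= 0)) {
    stop("column `age` must be positive and finite", call. = FALSE)
  }
  amy <- visits$modality == "amyloid"
  if (any(!is.finite(visits$abl[amy]))) {
    stop("column `abl` must be present on every amyloid row", call. = FALSE)
  }
  nft <- as.matrix(visits[visits$modality == "tau", paste0("nft", 1:6)])
  if (nrow(nft) && (any(!is.finite(nft)) || any(nft <= 0))) {
    stop("columns `nft1`..`nft6` must be positive on every tau row",
         call. = FALSE)
  }
  bad <- vapply(split(visits$age[amy], visits$subject_id[amy]),
                function(a) length(a) > 1L && any(diff(sort(a)) <= 0),
                logical(1))
  if (any(bad)) {
    stop("amyloid visit ages must be distinct within subject(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  visits
}

#' Write / read a cohort visit table as CSV
#'
#' `write_cohort()` writes the long-format table with empty fields for missing
#' values and, when a config is supplied, a JSON sidecar (`<path>.json`)
#' echoing every generator setting and the seed. `read_cohort()` reads and
#' validates the same layout.
#'
#' @param visits Cohort table.
#' @param path Output CSV path.
#' @param config Optional [cohort_config()] echoed to the sidecar.
#' @return The path (write) or validated data.frame (read).
#' @export
write_cohort <- function(visits, path, config = NULL) {
  utils::write.csv(visits, path, row.names = FALSE, na = "")
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  for (nm in intersect(cohort_columns(), names(df))) {
    if (nm %in% c("subject_id", "modality")) next
    df[[nm]] <- as.numeric(df[[nm]])
  }
  validate_cohort(df)
}
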