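nft_stages <- function() c("I", "II", "III", "IV", "V", "VI")

chronicity_bin_levels <- function() c("<0", "0-2.5", "2.5-5", "5-10", ">10")

#' Aggregate regional SUVRs into an NFT-stage profile
#'
#' Combines FreeSurfer-style regional SUVRs into the six composite NFT-stage
#' SUVRs by volume-weighted averaging over each stage's member regions.
#' Regions absent from `stage_map` are ignored.
#'
#' @param region_table Data.frame with columns `region`, `suvr`, `volume`.
#' @param stage_map Named character/integer vector mapping region name to
#'   stage (`"I"`..`"VI"` or 1..6).
#' @return Named numeric vector of six stage SUVRs (`nft1`..`nft6`).
#' @export
#' @examples
#' regions <- data.frame(region = c("a", "b"), suvr = c(1, 2), volume = c(3, 1))
#' aggregate_nft_stage_suvr(regions, c(a = "I", b = "I")) # nft1 = 1.25
aggregate_nft_stage_suvr <- function(region_table, stage_map) {
  stopifnot(all(c("region", "suvr", "volume") %in% names(region_table)))
  mapped <- region_table[region_table$region %in% names(stage_map), ]
  if (any(mapped$volume <= 0)) {
    stop("mapped regions must have positive volume", call. = FALSE)
  }
  stage <- stage_map[mapped$region]
  if (is.numeric(stage)) stage <- nft_stages()[stage]
  out <- stats::setNames(rep(NA_real_, 6L), paste0("nft", 1:6))
  for (k in seq_len(6L)) {
    sel <- stage == nft_stages()[k]
    if (!any(sel)) {
      stop("no member regions mapped to NFT stage ", nft_stages()[k],
           call. = FALSE)
    }
    out[k] <- stats::weighted.mean(mapped$suvr[sel], mapped$volume[sel])
  }
  out
}

#' Assign an A+ chronicity bin
#'
#' Bins chronicity (years) into the five analysis bins `<0`, `0-2.5`,
#' `2.5-5`, `5-10`, `>10`. Intervals are left-closed, right-open, so a
#' chronicity of exactly 2.5 falls in `2.5-5` and exactly 10 in `>10`.
#'
#' @param chronicity Finite chronicity value(s) in years.
#' @return Factor with the five bin levels.
#' @export
#' @examples
#' assign_chronicity_bin(c(-0.01, 0, 2.5, 9.99, 10))
assign_chronicity_bin <- function(chronicity) {
  check_finite(chronicity, "chronicity")
  cut(chronicity, breaks = c(-Inf, 0, 2.5, 5, 10, Inf),
      labels = chronicity_bin_levels(), right = FALSE)
}

#' Annualized tau change between two scans
#'
#' Absolute rate `(followup - baseline)/dt` in SUVR/yr and percent rate
#' relative to baseline, `100 * (followup - baseline)/(baseline * dt)` in
#' %/yr.
#'
#' @param baseline,followup SUVR value(s); baseline must be positive.
#' @param dt Scan interval(s) in years, positive.
#' @return List with `rate` and `pct_rate`.
#' @export
#' @examples
#' annualized_change(1.0, 1.1, 2.0) # rate 0.05, pct_rate 5
annualized_change <- function(baseline, followup, dt) {
  check_finite(baseline, "baseline")
  check_finite(followup, "followup")
  check_finite(dt, "dt")
  if (any(dt <= 0)) stop("`dt` must be positive", call. = FALSE)
  if (any(baseline <= 0)) stop("`baseline` must be positive", call. = FALSE)
  delta <- followup - baseline
  list(rate = delta / dt, pct_rate = 100 * delta / (baseline * dt))
}

#' Cohen's d with a 95% confidence interval
#'
#' Independent-groups standardized mean difference between follow-up and
#' baseline SUVR lists: `d = (mean(followup) - mean(baseline)) / pooled SD`,
#' positive when follow-up exceeds baseline. The CI uses the normal
#' approximation `d +/- 1.96 * se` with
#' `se = sqrt(2/n + d^2 / (4 * (2n - 2)))`.
#'
#' @param baseline,followup Equal-length numeric vectors, `n >= 2`.
#' @return List with `d`, `ci_low`, `ci_high`, `n`. All `NA` (with a warning)
#'   when the pooled SD is zero.
#' @export
#' @examples
#' cohens_d_ci(c(0, 1), c(1, 2)) # d = 1.414
cohens_d_ci <- function(baseline, followup) {
  n <- length(baseline)
  if (length(followup) != n || n < 2L) {
    stop("`baseline` and `followup` must have equal length >= 2",
         call. = FALSE)
  }
  check_finite(baseline, "baseline")
  check_finite(followup, "followup")
  sp <- sqrt(((n - 1) * stats::var(baseline) + (n - 1) * stats::var(followup)) /
               (2 * n - 2))
  if (sp == 0) {
    warning("pooled SD is zero; effect size undefined", call. = FALSE)
    return(list(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  d <- (mean(followup) - mean(baseline)) / sp
  se <- sqrt(2 / n + d^2 / (4 * (2 * n - 2)))
  list(d = d, ci_low = d - 1.96 * se, ci_high = d + 1.96 * se, n = n)
}

#' Pearson correlation with a Fisher-z 95% confidence interval
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`, each with nonzero
#'   variance.
#' @return List with `r`, `ci_low`, `ci_high`, `n`. The CI is
#'   `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`; degenerate at `r = +/-1`.
#' @export
#' @examples
#' x <- 1:10
#' pearson_ci(x, 2 * x + 1) # r = 1, CI [1, 1]
pearson_ci <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 4L) {
    stop("`x` and `y` must have equal length >= 4", call. = FALSE)
  }
  check_finite(x, "x")
  check_finite(y, "y")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  hw <- 1.96 / sqrt(n - 3)
  list(r = r, ci_low = tanh(z - hw), ci_high = tanh(z + hw), n = n)
}

#' Summarize longitudinal tau change within one chronicity bin
#'
#' Per NFT stage: mean annualized percent change with a t-distribution 95% CI
#' (`mean +/- t[0.975, n-1] * sd / sqrt(n)`; `NA` bounds for a single record)
#' and the Cohen's d effect size between the baseline and follow-up SUVR
#' lists. Also reports the bin's subject count and mean baseline amyloid
#' burden in Centiloids.
#'
#' @param records Data.frame of tau-change records (one row per subject x
#'   stage) with columns `subject_id`, `stage`, `baseline_suvr`,
#'   `followup_suvr`, `pct_rate`, `baseline_cl`, `chronicity_bin`.
#' @return Data.frame with one row per stage: `chronicity_bin`, `stage`, `n`,
#'   `mean_burden_cl`, `mean_pct_rate`, `pct_ci_low`, `pct_ci_high`,
#'   `cohens_d`, `d_ci_low`, `d_ci_high`.
#' @export
summarize_bin <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("empty chronicity bin", call. = FALSE)
  }
  bin <- as.character(records$chronicity_bin[1L])
  subj <- unique(records$subject_id)
  burden <- mean(records$baseline_cl[!duplicated(records$subject_id)])
  out <- lapply(nft_stages(), function(st) {
    d <- records[records$stage == st, ]
    n <- nrow(d)
    if (n == 0L) {
      return(data.frame(chronicity_bin = bin, stage = st, n = 0L,
                        mean_burden_cl = burden, mean_pct_rate = NA_real_,
                        pct_ci_low = NA_real_, pct_ci_high = NA_real_,
                        cohens_d = NA_real_, d_ci_low = NA_real_,
                        d_ci_high = NA_real_))
    }
    m <- mean(d$pct_rate)
    if (n >= 2L) {
      hw <- stats::qt(0.975, n - 1) * stats::sd(d$pct_rate) / sqrt(n)
      ci <- c(m - hw, m + hw)
      es <- suppressWarnings(cohens_d_ci(d$baseline_suvr, d$followup_suvr))
    } else {
      ci <- c(NA_real_, NA_real_)
      es <- list(d = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
    }
    data.frame(chronicity_bin = bin, stage = st, n = n,
               mean_burden_cl = burden, mean_pct_rate = m,
               pct_ci_low = ci[1], pct_ci_high = ci[2],
               cohens_d = es$d, d_ci_low = es$ci_low, d_ci_high = es$ci_high)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# chronicity of every tau scan, via rigid alignment to the subject's
# reference-scan estimate; errors list subjects missing from `estimates`
tau_with_chronicity <- function(tau, estimates) {
  orphans <- setdiff(unique(tau$subject_id), estimates$subject_id)
  if (length(orphans)) {
    stop("tau scans with no chronicity estimate for subject(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  i <- match(tau$subject_id, estimates$subject_id)
  tau$chronicity <- estimates$chronicity_at_reference[i] +
    (tau$age - estimates$reference_age[i])
  tau
}

# nearest-in-age amyloid burden for each tau scan (co-scheduled scans match
# exactly)
nearest_amyloid <- function(tau, amy) {
  vapply(seq_len(nrow(tau)), function(j) {
    a <- amy[amy$subject_id == tau$subject_id[j], ]
    a$abl[which.min(abs(a$age - tau$age[j]))]
  }, numeric(1))
}

#' Tau-versus-chronicity analysis for a cohort
#'
#' Joins tau scans to per-subject chronicity estimates (rigid age alignment)
#' and produces:
#' * cross-sectional Pearson correlations (with Fisher-z 95% CIs) of each NFT
#'   stage's baseline SUVR against chronological age, amyloid load, and A+
#'   chronicity;
#' * longitudinal tau-change records (one per subject x stage) for subjects
#'   with two tau scans: annualized SUVR rate and percent change, binned by
#'   chronicity at the baseline tau scan;
#' * per-bin summaries across the five chronicity bins (bins with no
#'   longitudinal subjects yield `n = 0` rows so the output always spans all
#'   5 bins x 6 stages).
#'
#' @param visits Cohort visit table.
#' @param estimates Per-subject chronicity estimates (from
#'   [estimate_cohort_chronicity()]).
#' @return List with `correlations`, `tau_change`, `bin_summary`.
#' @export
run_tau_analysis <- function(visits, estimates) {
  validate_cohort(visits)
  tau <- visits[visits$modality == "tau", ]
  amy <- visits[visits$modality == "amyloid", ]
  empty_cor <- data.frame(predictor = character(), stage = character(),
                          r = numeric(), ci_low = numeric(),
                          ci_high = numeric(), n = integer())
  if (nrow(tau) == 0L) {
    warning("cohort contains no tau scans; returning empty analysis",
            call. = FALSE)
    return(list(correlations = empty_cor,
                tau_change = NULL,
                bin_summary = NULL))
  }
  tau <- tau_with_chronicity(tau, estimates)
  tau <- tau[order(tau$subject_id, tau$age), ]
  tau$abl_at_scan <- nearest_amyloid(tau, amy)

  base <- tau[!duplicated(tau$subject_id), ]
  preds <- list(age = base$age, abl = base$abl_at_scan,
                chronicity = base$chronicity)
  correlations <- do.call(rbind, lapply(names(preds), function(p) {
    do.call(rbind, lapply(seq_len(6L), function(k) {
      ci <- pearson_ci(preds[[p]], base[[paste0("nft", k)]])
      data.frame(predictor = p, stage = nft_stages()[k], r = ci$r,
                 ci_low = ci$ci_low, ci_high = ci$ci_high, n = ci$n)
    }))
  }))

  nscan <- table(tau$subject_id)
  long_ids <- names(nscan)[nscan >= 2L]
  if (length(long_ids) == 0L) {
    warning("no subject with two tau scans; longitudinal stage skipped",
            call. = FALSE)
    return(list(correlations = correlations, tau_change = NULL,
                bin_summary = NULL))
  }
  records <- do.call(rbind, lapply(long_ids, function(id) {
    d <- tau[tau$subject_id == id, ]
    b <- d[1L, ]
    f <- d[nrow(d), ]
    dt <- f$age - b$age
    do.call(rbind, lapply(seq_len(6L), function(k) {
      ch <- annualized_change(b[[paste0("nft", k)]], f[[paste0("nft", k)]], dt)
      data.frame(subject_id = id, stage = nft_stages()[k],
                 baseline_suvr = b[[paste0("nft", k)]],
                 followup_suvr = f[[paste0("nft", k)]],
                 dt = dt, rate = ch$rate, pct_rate = ch$pct_rate,
                 chronicity_baseline = b$chronicity,
                 chronicity_bin = as.character(assign_chronicity_bin(b$chronicity)),
                 baseline_cl = abl_to_cl(b$abl_at_scan))
    }))
  }))
  rownames(records) <- NULL

  bin_summary <- do.call(rbind, lapply(chronicity_bin_levels(), function(bn) {
    d <- records[records$chronicity_bin == bn, ]
    if (nrow(d) == 0L) {
      return(data.frame(chronicity_bin = bn, stage = nft_stages(), n = 0L,
                        mean_burden_cl = NA_real_, mean_pct_rate = NA_real_,
                        pct_ci_low = NA_real_, pct_ci_high = NA_real_,
                        cohens_d = NA_real_, d_ci_low = NA_real_,
                        d_ci_high = NA_real_))
    }
    summarize_bin(d)
  }))
  rownames(bin_summary) <- NULL

  list(correlations = correlations, tau_change = records,
       bin_summary = bin_summary)
}
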