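#' Discrete rate-versus-burden samples from longitudinal amyloid data
#'
#' First stage of the SILA procedure: for every subject with at least two
#' amyloid scans, convert serial burden measurements into discrete samples of
#' the accumulation rate as a function of burden. The default strategy takes
#' adjacent-scan finite differences, assigning `(abl2 - abl1)/(age2 - age1)`
#' at the pair's midpoint burden, which preserves within-subject curvature
#' across 3-5 scans. The alternative `"subject_slope"` strategy fits one OLS
#' slope per subject (assigned at the subject's mean burden).
#'
#' @param visits Cohort visit table (see [generate_cohort()]).
#' @param method Sampling strategy: `"adjacent_pairs"` (default) or
#'   `"subject_slope"`.
#' @return A data.frame with columns `subject_id`, `burden`, `rate`, `weight`
#'   (number of scans behind the sample).
#' @export
compute_rate_samples <- function(visits,
                                 method = c("adjacent_pairs", "subject_slope")) {
  method <- match.arg(method)
  validate_cohort(visits)
  amy <- visits[visits$modality == "amyloid", ]
  amy <- amy[order(amy$subject_id, amy$age), ]
  per <- split(amy, amy$subject_id)
  per <- per[vapply(per, nrow, 0L) >= 2L]
  if (length(per) == 0L) {
    stop("no subject with >= 2 amyloid scans; cannot estimate the rate field",
         call. = FALSE)
  }
  out <- lapply(per, function(d) {
    if (any(diff(d$age) <= 0)) {
      stop("non-increasing scan ages for subject ", d$subject_id[1],
           call. = FALSE)
    }
    if (method == "adjacent_pairs") {
      k <- nrow(d)
      data.frame(subject_id = d$subject_id[1],
                 burden = (d$abl[-1] + d$abl[-k]) / 2,
                 rate = diff(d$abl) / diff(d$age),
                 weight = 2L)
    } else {
      fit <- stats::lm.fit(cbind(1, d$age), d$abl)
      data.frame(subject_id = d$subject_id[1],
                 burden = mean(d$abl),
                 rate = fit$coefficients[2],
                 weight = nrow(d))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Construct a rate field on a burden grid
#'
#' Internal-style constructor used for hand-built fields (tests, analytic
#' comparisons). `grid_burden` must be strictly increasing; `sd_rate` and
#' `n_per_window` default to zeros.
#'
#' @param grid_burden Strictly increasing burden grid (load units).
#' @param mean_rate Rate at each grid point (load units/yr).
#' @param sd_rate Rate SD at each grid point.
#' @param n_per_window Sample count behind each grid point.
#' @return An object of class `sila_rate_field`.
#' @export
rate_field <- function(grid_burden, mean_rate,
                       sd_rate = rep(0, length(grid_burden)),
                       n_per_window = rep(0L, length(grid_burden))) {
  if (length(grid_burden) < 2L || any(diff(grid_burden) <= 0)) {
    stop("grid_burden must be strictly increasing with >= 2 points",
         call. = FALSE)
  }
  stopifnot(length(mean_rate) == length(grid_burden),
            length(sd_rate) == length(grid_burden),
            all(sd_rate >= 0))
  structure(list(grid_burden = as.numeric(grid_burden),
                 mean_rate = as.numeric(mean_rate),
                 sd_rate = as.numeric(sd_rate),
                 n_per_window = as.integer(n_per_window)),
            class = "sila_rate_field")
}

#' Smooth rate samples into a mean rate field over burden
#'
#' At each grid burden, averages the rate samples whose burden lies within
#' `window/2` on either side, recording the window SD and sample count. Grid
#' points with empty windows are filled by linear interpolation between the
#' nearest populated neighbours (constant extrapolation at the ends). The mean
#' rate is finally clipped below at `rate_floor` so the integrated trajectory
#' stays strictly monotone and invertible.
#'
#' @param samples Output of [compute_rate_samples()].
#' @param grid Strictly increasing burden grid; default: unit steps spanning
#'   the sampled burden range.
#' @param window Full window width in load units (default 5).
#' @param rate_floor Lower clip for the smoothed mean rate (load units/yr).
#' @return A `sila_rate_field` with `grid_burden`, `mean_rate`, `sd_rate`,
#'   `n_per_window`.
#' @export
fit_rate_field <- function(samples, grid = NULL, window = 5,
                           rate_floor = 0.01) {
  if (is.null(samples) || nrow(samples) == 0L) {
    stop("no rate samples supplied", call. = FALSE)
  }
  stopifnot(all(is.finite(samples$burden)), all(is.finite(samples$rate)),
            window > 0, rate_floor >= 0)
  if (is.null(grid)) {
    grid <- seq(floor(min(samples$burden)), ceiling(max(samples$burden)), by = 1)
  }
  if (length(grid) < 2L || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing with >= 2 points", call. = FALSE)
  }
  half <- window / 2
  stats_at <- function(g) {
    r <- samples$rate[abs(samples$burden - g) <= half]
    c(mean = if (length(r)) mean(r) else NA_real_,
      sd = if (length(r) >= 2L) stats::sd(r) else if (length(r)) 0 else NA_real_,
      n = length(r))
  }
  m <- vapply(grid, stats_at, numeric(3))
  mean_rate <- m["mean", ]
  sd_rate <- m["sd", ]
  n_win <- as.integer(m["n", ])
  if (all(is.na(mean_rate))) {
    stop("all smoothing windows are empty; widen `window` or the grid",
         call. = FALSE)
  }
  fill <- function(v) {
    ok <- !is.na(v)
    if (all(ok)) return(v)
    stats::approx(grid[ok], v[ok], xout = grid, rule = 2)$y
  }
  mean_rate <- pmax(fill(mean_rate), rate_floor)
  sd_rate <- fill(sd_rate)
  rate_field(grid, mean_rate, sd_rate, n_win)
}

#' Integrate a rate field into a burden-versus-chronicity curve
#'
#' Euler integration of the rate-versus-burden field, forward and backward in
#' disease time from the anchor (chronicity 0 years at the A+ cutoff, 13.3
#' load units). The rate at any burden is obtained by linear interpolation on
#' the field grid (constant beyond its ends). Each direction takes up to
#' `max_iter` steps of `step` years -- 50 years of modeled disease time per
#' direction at the defaults -- and terminates early if the interpolated rate
#' becomes non-positive.
#'
#' @param field A `sila_rate_field`.
#' @param anchor_abl Burden at chronicity 0 (default: the A+ cutoff).
#' @param step Euler step size in years (default 0.25).
#' @param max_iter Maximum iterations per direction (default 200).
#' @return A data.frame of class `sila_curve` with strictly increasing
#'   `chronicity`, strictly increasing `abl`, and `cl`; attributes `anchor`,
#'   `step`.
#' @export
integrate_trajectory <- function(field, anchor_abl = cl_constants()$cutoff_abl,
                                 step = 0.25, max_iter = 200L) {
  stopifnot(inherits(field, "sila_rate_field"), step > 0, max_iter >= 1L)
  ratef <- stats::approxfun(field$grid_burden, field$mean_rate, rule = 2)
  if (ratef(anchor_abl) <= 0) {
    stop("rate at the anchor burden is non-positive; curve is degenerate",
         call. = FALSE)
  }
  march <- function(dir) {
    a <- anchor_abl
    out <- numeric(0)
    for (i in seq_len(max_iter)) {
      r <- ratef(a)
      if (r <= 0) break
      a <- a + dir * step * r
      out <- c(out, a)
    }
    out
  }
  fwd <- march(+1)
  bwd <- march(-1)
  chron <- c(-step * rev(seq_along(bwd)), 0, step * seq_along(fwd))
  abl <- c(rev(bwd), anchor_abl, fwd)
  if (any(diff(abl) <= 0)) {
    stop("integrated burden is not strictly increasing", call. = FALSE)
  }
  curve <- data.frame(chronicity = chron, abl = abl, cl = abl_to_cl(abl))
  class(curve) <- c("sila_curve", "data.frame")
  attr(curve, "anchor") <- c(chronicity = 0, abl = anchor_abl)
  attr(curve, "step") <- step
  curve
}

#' Invert a trajectory curve: chronicity at a given burden
#'
#' Monotone piecewise-linear inversion of the burden-versus-chronicity curve.
#' Burdens outside the modeled range are truncated to the earliest/latest
#' modeled chronicity and flagged.
#'
#' @param curve A `sila_curve`.
#' @param abl Burden value(s) to invert.
#' @return A data.frame with `chronicity`, `truncated_low`, `truncated_high`.
#' @export
chronicity_at_burden <- function(curve, abl) {
  check_finite(abl, "abl")
  lo <- min(curve$abl)
  hi <- max(curve$abl)
  clamped <- pmin(pmax(abl, lo), hi)
  data.frame(
    chronicity = stats::approx(curve$abl, curve$chronicity, xout = clamped)$y,
    truncated_low = abl < lo,
    truncated_high = abl > hi)
}

#' A+ chronicity and estimated onset age for one subject
#'
#' Aligns a subject's amyloid scans to the population burden-versus-time
#' curve:
#' * single scan: chronicity is the curve inverted at that scan's burden
#'   (`inverted_single_scan`), regardless of A+ status;
#' * multiple scans with at least one A+ scan: the first A+ scan (earliest
#'   age; boundary value 13.3 counts as A+) is the reference and is inverted
#'   (`aligned_first_apositive`) -- the subject's observed time axis is then
#'   rigidly attached to the curve at that point;
#' * multiple scans, never A+: the most recent scan is inverted
#'   (`aligned_most_recent_subthreshold`).
#'
#' A reference burden below the modeled range is truncated to the earliest
#' modeled chronicity and reported with method `truncated_below_range`; above
#' the range, to the latest modeled chronicity with `truncated = TRUE`. The
#' estimated A+ onset age is the reference age minus the chronicity at the
#' reference scan, exactly.
#'
#' @param subject_visits Visit rows for one subject (tau rows ignored).
#' @param curve A `sila_curve`.
#' @param cutoff A+ cutoff in load units.
#' @return One-row data.frame: `subject_id`, `reference_age`,
#'   `chronicity_at_reference`, `estimated_onset_age`, `method`, `truncated`.
#' @export
estimate_chronicity <- function(subject_visits, curve,
                                cutoff = cl_constants()$cutoff_abl) {
  amy <- subject_visits[subject_visits$modality == "amyloid", ]
  if (nrow(amy) == 0L) {
    stop("subject has no amyloid scans", call. = FALSE)
  }
  amy <- amy[order(amy$age), ]
  if (nrow(amy) == 1L) {
    ref <- 1L
    method <- "inverted_single_scan"
  } else if (any(amy$abl >= cutoff)) {
    ref <- which(amy$abl >= cutoff)[1L]
    method <- "aligned_first_apositive"
  } else {
    ref <- nrow(amy)
    method <- "aligned_most_recent_subthreshold"
  }
  inv <- chronicity_at_burden(curve, amy$abl[ref])
  truncated <- inv$truncated_low || inv$truncated_high
  if (inv$truncated_low) method <- "truncated_below_range"
  data.frame(subject_id = amy$subject_id[1L],
             reference_age = amy$age[ref],
             chronicity_at_reference = inv$chronicity,
             estimated_onset_age = amy$age[ref] - inv$chronicity,
             method = method,
             truncated = truncated)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Fit the SILA model and estimate chronicity for a whole cohort
#'
#' Orchestrates the full procedure: rate samples from multi-scan subjects,
#' smoothed rate field over burden, Euler-integrated burden-versus-chronicity
#' curve anchored at the A+ cutoff, and per-subject chronicity / onset-age
#' estimates. Deterministic for fixed input and settings; the result does not
#' depend on the row order of `visits`. Errors are annotated with the stage
#' that raised them.
#'
#' @param visits Cohort visit table.
#' @param method Rate sampling strategy (see [compute_rate_samples()]).
#' @param grid,window,rate_floor Rate-field settings (see [fit_rate_field()]).
#' @param step,max_iter Integration settings (see [integrate_trajectory()]).
#' @param cutoff A+ cutoff in load units.
#' @return A list with `estimates` (one row per subject, ordered by id),
#'   `curve`, `field`, and `samples`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 30,
#'   scan_count_distribution = c(`2` = 20, `3` = 10),
#'   tau_subset_distribution = c(`2` = 10)))
#' fit <- estimate_cohort_chronicity(cohort)
#' head(fit$estimates)
estimate_cohort_chronicity <- function(visits,
                                       method = "adjacent_pairs",
                                       grid = NULL, window = 5,
                                       rate_floor = 0.01,
                                       step = 0.25, max_iter = 200L,
                                       cutoff = cl_constants()$cutoff_abl) {
  visits <- with_stage("schema", validate_cohort(visits))
  samples <- with_stage("rate_samples",
                        compute_rate_samples(visits, method = method))
  field <- with_stage("rate_field",
                      fit_rate_field(samples, grid = grid, window = window,
                                     rate_floor = rate_floor))
  curve <- with_stage("integration",
                      integrate_trajectory(field, anchor_abl = cutoff,
                                           step = step, max_iter = max_iter))
  amy <- visits[visits$modality == "amyloid", ]
  per <- split(amy, amy$subject_id)
  est <- with_stage("chronicity", do.call(rbind, lapply(per, function(d) {
    estimate_chronicity(d, curve, cutoff = cutoff)
  })))
  est <- est[order(est$subject_id), ]
  rownames(est) <- NULL
  list(estimates = est, curve = curve, field = field, samples = samples)
}
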