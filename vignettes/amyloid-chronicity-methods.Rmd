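---
title: "Modeling amyloid chronicity and the emergence of tau: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling amyloid chronicity and the emergence of tau: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amychron)
```

## The problem

Adults with Down syndrome are genetically predisposed to Alzheimer's-disease
pathology, but the age at which amyloid-beta becomes abnormal varies by
decades across individuals (roughly 30 to 60 years). Chronological age is
therefore a poor disease clock. A better clock is **A+ chronicity**: the
number of years an individual has been amyloid-positive. Chronicity is 0 at
the positivity cutoff, negative before it, and — unlike age — directly tied
to the individual's own biomarker trajectory.

`amychron` implements the full chain needed to study this at desk scale:

1. a synthetic-cohort generator that emulates a longitudinal Down-syndrome
   PET study design (so every downstream stage is testable without
   restricted data),
2. amyloid burden metrics (amyloid-load/Centiloid conversion, A+
   classification, voxelwise two-template load estimation),
3. the SILA trajectory model (sampled iterative local approximation) that
   converts serial amyloid measurements into a population
   burden-versus-time curve and per-person chronicity and onset-age
   estimates, and
4. the downstream tau analysis: correlations and chronicity-binned
   longitudinal change across the six NFT (neurofibrillary-tangle) stage
   composites.

## Units and scales

Global amyloid burden is carried in **amyloid-load units** (column `abl`), a
template-based metric that suppresses nonspecific binding. It maps linearly
to the standardized **Centiloid** scale:

$$\mathrm{CL} = 2.27\,\mathrm{A\beta_L} - 12.1$$

The early-positivity cutoff is 13.3 load units, which this map sends to
18.091 CL (reported as ~18 CL; the 0.09 CL rounding discrepancy in the
published calibration is accepted and documented in `cl_constants()`). A+
classification is boundary-inclusive: chronicity 0 *is* the cutoff.

Tau is carried as SUVR (standardized uptake value ratio, cerebellar
gray-matter reference) in six composite regions mirroring Braak's
neurofibrillary staging, NFT I–VI.

## The SILA model

The model rests on one assumption: the *rate* of amyloid accumulation is a
function of the current *burden*, not of age. Then every accumulator rides
the same trajectory, merely time-shifted, and longitudinal data from many
individuals can be stitched into one curve.

**Rate sampling.** For each subject with at least two amyloid scans, each
adjacent scan pair contributes one sample: rate $\Delta A/\Delta t$ assigned
at the pair's midpoint burden. Pairwise sampling (the default) preserves
within-subject curvature across 3–5 scans; a per-subject OLS-slope strategy
is available as `method = "subject_slope"` for sensitivity analyses. This
choice is genuinely open — published summaries of the algorithm do not pin
down the sampling scheme — so both are implemented and the pairwise form is
the default.

**Rate field.** Samples are smoothed over burden with a moving window
(default: full width 5 load units on a 1-unit grid). Empty windows are
filled by linear interpolation between populated neighbours, with constant
extrapolation at the ends. The smoothed mean rate is clipped below at a
small positive floor (default 0.01 load units/yr): the integration
terminates on a non-positive slope, and a zero-rate plateau would make the
curve non-invertible where individual scans must be aligned to it. The floor
only matters far below the cutoff, where observed drift is small.

**Integration.** The curve is built by Euler's method with a 0.25-year step
and at most 200 iterations per direction — 50 years of modeled disease time
forward from the anchor (chronicity 0 years, 13.3 load units) and up to the
same span backward. The 200-iteration cap is interpreted per direction: the
forward branch covers the full 50 years of modeled disease time, and the
backward branch terminates on the same cap or at the rate floor. Within a step the
rate is evaluated by linear interpolation on the field grid.

Forward Euler at a 0.25-year step is first-order accurate: against an
analytic logistic benchmark ($\rho = 0.1/\mathrm{yr}$, $K = 100$ through the
anchor) the maximum deviation is about 0.24 load units, peaking mid-rise,
and halves when the step halves. The tests assert exactly this measured
behaviour; the method is kept at the 0.25-year Euler step rather than
upgraded to a higher-order scheme, because the step *is* part of the
procedure being reproduced.

**Individual alignment.** With the curve in hand (strictly increasing, so
its inverse is well defined by monotone piecewise-linear interpolation):

* single-scan subjects: invert the curve at the scan's burden,
* multi-scan subjects with an A+ scan: the first A+ scan (ties broken by
  earliest age) is the reference; its inversion pins the subject's observed
  time axis rigidly to the curve,
* multi-scan subjects who never reach A+: the most recent scan is inverted.

Burdens outside the modeled range are truncated to the nearest modeled
chronicity and flagged. The estimated A+ onset age is exactly
`reference_age - chronicity_at_reference`.

## The synthetic cohort

The generator is first-class, tested code; its defaults are the study
conditions, not tuning knobs.

* **Design:** 177 subjects; amyloid scan counts drawn to match the
  1/2/3/4/5-scan distribution 58/64/15/30/10 exactly; visits every 2–3
  years (uniform); 75 subjects with one tau scan and 92 with two,
  co-scheduled with amyloid visits (two-tau subjects: first and last visit).
* **Ages:** first-visit age $\mathcal N(36, 8.5^2)$ truncated to [25, 70].
  The mean sits below the target cohort mean because follow-up visits add
  ~2.4 years to the average scan age and left-truncation at 25 adds ~0.6,
  bringing the all-scan age distribution to ≈ 40 ± 8 years. The lower bound
  encodes the ≥ 25-year inclusion criterion.
* **Amyloid:** latent burden solves $dA/dt = r(A)$ with a sigmoid-in-burden
  rate law rising from 0.2 load units/yr pre-onset to a plateau of 3.73
  load units/yr (midpoint 30, width 8 load units), time-shifted to cross
  13.3 exactly at the subject's onset age ($\mathcal N(41, 7^2)$ truncated
  to [25, 70], giving onsets spanning roughly 30–60). A sigmoid in *burden*
  (not a logistic in time) is used deliberately: the rate plateaus at high
  burden while burden itself keeps rising, matching the observed absence of
  a burden plateau. Measurement noise is additive Gaussian (SD 1.5 load
  units), homoscedastic for simplicity — no noise model is reported for
  these measurements, so this is an assumption, exposed in the config.
* **Tau:** stage SUVR follows a hinge: flat at a stage baseline until
  chronicity exceeds a stage lag (0, 0, 1, 3, 4, 5 years for NFT I–VI),
  then linear at a stage slope (0.040 down to 0.020 SUVR/yr). Lags
  non-decreasing and slopes non-increasing across stages encode the
  Braak-like spatiotemporal ordering: early stages rise first and fastest.
  Baselines (1.20, 1.25, 1.15, 1.10, 1.05, 1.00 SUVR) and slopes put
  annualized change in the observed few-percent-per-year range. Noise:
  Gaussian, SD 0.05 SUVR.

**What the generator does *not* emulate:** voxel-level images (a flat CSV
voxel fixture exercises the voxelwise estimator separately), APOE effects on
onset, dropout, site/scanner effects, heteroscedastic or
burden-dependent noise, choroid-plexus spill-in to NFT II, and
atrophy-driven late declines in medial-temporal SUVR. Passing tests
therefore demonstrate internal consistency of the pipeline under the stated
generative assumptions — parameter recovery, not external validity on real
cohorts.

## Tau analysis choices

* **Annualized % change** is relative to baseline:
  $100\,(f-b)/(b\,\Delta t)$ per stage. (The midpoint-relative alternative
  was not used; reported tables in this field rarely state the formula, so
  a convention had to be fixed.)
* **Chronicity bins** `<0, [0,2.5), [2.5,5), [5,10), [10,∞)` are
  left-closed/right-open; bin labels like "0–2.5" are ambiguous at shared
  endpoints, so a convention had to be fixed.
* **Bin CIs** are t-distribution intervals
  ($\bar x \pm t_{0.975,n-1}\,s/\sqrt n$); bootstrap intervals would be the main
  alternative, and the t form is the simplest defensible default at bin
  sizes of 5–60.
* **Cohen's d** is the independent-groups form with pooled SD and
  normal-approximation CI, $se = \sqrt{2/n + d^2/(4(2n-2))}$. This variant
  is the one whose standard error reproduces the wide intervals expected at
  bin sizes around n = 8 (d ≈ 1.0 with a CI spanning roughly −0.06 to 2.0),
  as opposed to the much tighter paired-design error.
* **Correlations** use Pearson's r with Fisher-z 95% CIs
  ($\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$). Comparisons
  between predictors (chronicity vs age) are descriptive — larger r — with
  no formal dependent-correlation test.
* **Stage composites** from regional data use volume-weighted means with a
  caller-supplied region-to-stage map (`aggregate_nft_stage_suvr()`); the
  exact FreeSurfer membership of each composite follows the tau-PET staging
  literature and is not hard-coded here.

## Numerical and degenerate-input behaviour

* The generator's latent ODE is solved with `deSolve` (lsoda) on a
  0.05-year grid and interpolated; the anchor value at onset is exact by
  construction. Tests cross-check against an independently coded fine-step
  RK4 integrator.
* The trajectory curve is strictly increasing by construction (positive
  clipped rates); integration halts on a non-positive interpolated rate.
* Inversion truncates out-of-range burdens and flags them rather than
  extrapolating.
* Voxelwise load estimation is unconstrained OLS via QR; collinear
  templates raise an error, negative fitted loads warn and report as-is.
* Zero pooled SD (Cohen's d) returns NA with a warning; constant inputs to
  the correlation raise an error; single-record bins report NA intervals.
* Problem sizes used throughout the test suite: the full 177-subject design
  for design-count and recovery checks (20 seed replicates for the
  multi-seed properties), 30-subject cohorts for mechanics, 2000
  simulations for CI-coverage calibration.

## Known limitations

* Chronicity estimates for subjects far below the cutoff lean on the
  backward branch of the curve, where the rate is small; measurement noise
  of 1.5 load units then translates into several years of chronicity
  uncertainty. This is inherent to the method (shallow slope), not to the
  implementation, and is why onset-age recovery is summarized by the
  cohort median.
* The rate field is an unweighted windowed mean; robust or
  measurement-error-aware smoothing is out of scope.
* No partial-volume or off-target-binding corrections are modeled or
  applied.
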