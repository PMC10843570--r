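# amychron

Amyloid-chronicity trajectory modeling and longitudinal tau staging for
adult Down-syndrome PET cohorts.

People with Down syndrome develop Alzheimer's-type amyloid and tau pathology
almost universally, but the age at which amyloid becomes abnormal spans
roughly 30–60 years — so chronological age is a poor disease clock.
`amychron` replaces age with **A+ chronicity**: the estimated number of
years an individual has been amyloid-positive. It is aimed at biomarker
methodologists and trialists who need an age-independent disease timeline
from longitudinal amyloid PET, plus the downstream machinery to relate that
timeline to tau accumulation across NFT (Braak-like) stage regions.

## The model

Amyloid burden is measured in amyloid-load units (`abl`), linearly related
to Centiloids by `CL = 2.27·AβL − 12.1`; the A+ cutoff is 13.3 load units
(~18 CL). The SILA (sampled iterative local approximation) model assumes the
accumulation *rate* is a function of current *burden*:

1. every subject with ≥ 2 amyloid scans contributes discrete samples of
   `dA/dt` versus burden (adjacent-scan finite differences at midpoint
   burden);
2. the samples are smoothed into a mean rate field `r(A)` over a burden
   grid;
3. the field is integrated by Euler's method (0.25-yr step, 200 iterations
   per direction ⇒ 50 modeled years forward) from the anchor
   (chronicity 0 yr, 13.3 load units) into a monotone burden-versus-time
   curve `A(t)`;
4. each subject is aligned to the curve — single scans by inverting `A(t)`
   at the observed burden, multi-scan subjects at their first A+ scan (or
   most recent scan if never A+) — giving a chronicity at the reference
   scan and an estimated onset age `reference_age − chronicity`.

Longitudinal tau change (annualized % change and Cohen's d between baseline
and follow-up SUVR, per NFT stage I–VI) is then summarized in chronicity
bins `<0, 0–2.5, 2.5–5, 5–10, >10` years, alongside Pearson correlations
(Fisher-z CIs) of stage SUVR against age, burden, and chronicity.

A synthetic-cohort generator (`cohort_config()` / `generate_cohort()`)
reproduces the study design the analysis assumes — 177 subjects with a
58/64/15/30/10 distribution of 1–5 amyloid scans, 75/92 one/two tau scans,
visits every 2–3 years, heterogeneous onset ages, a rate law that plateaus
at 3.73 load units/yr — so the whole pipeline is testable without any
restricted data.

## Worked example

The numbered drivers under `analysis/` run the three stages and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 1
Rscript analysis/02_fit_sila.R
Rscript analysis/03_tau_analysis.R
```

The first simulates the cohort and reports its design:

```
cohort: 177 subjects, 401 amyloid scans, 259 tau scans
amyloid scans per subject: 1:58 2:64 3:15 4:30 5:10
scan age 41.1 (8.3) years; 188/401 scans A+
```

The second fits the SILA model:

```
rate at the A+ cutoff: 0.76 load units/yr (1.72 CL/yr)
modeled disease time: -50.0 to 50.0 years; curve spans -3.6-150.2 load units
estimates per method:
         aligned_first_apositive aligned_most_recent_subthreshold
                              67                               52
            inverted_single_scan
                              58
median |estimated - true| onset age: 1.82 years (n = 177)
```

i.e. with measurement noise of 1.5 load units the model recovers each
subject's (synthetic) true A+ onset age with a median error under 2 years.
The third stage prints the tau summaries; the load-bearing pattern is in the
annualized % change by chronicity bin (rows) and NFT stage (columns):

```
   chronicity_bin mean_pct_rate.I mean_pct_rate.II mean_pct_rate.III
1              <0            0.19             0.31            -0.078
7           0-2.5            2.90             3.26             1.966
13          2.5-5            4.21             2.51             1.830
```

Before A+ (`<0`) tau is flat; within 0–2.5 years of crossing the amyloid
cutoff, stages I–III are already rising at 2–3%/yr — the early-emergence
signature the chronicity timeline is designed to expose. The equivalent
Cohen's d table shows the same transition from small (<0.5) to large (>0.8)
effect sizes at A+ onset.

Equivalent programmatic access: `run_pipeline(cohort_config(seed = 1))`.

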