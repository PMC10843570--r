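Package: amychron
Title: Amyloid Chronicity Trajectory Modeling and Longitudinal Tau Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models longitudinal amyloid PET trajectories with a sampled
    iterative local approximation (SILA): the rate of amyloid accumulation is
    estimated as a function of amyloid burden from serial scans, integrated by
    Euler's method into a burden-versus-time curve anchored at the
    amyloid-positivity cutoff, and inverted to assign each individual an A+
    chronicity (years amyloid positive) and an estimated age of A+ onset.
    Includes a synthetic longitudinal cohort generator emulating a
    Down-syndrome PET study design, amyloid-load/Centiloid conversion and
    voxelwise amyloid-load estimation, and downstream analysis of longitudinal
    tau change across neurofibrillary-tangle (NFT) stage regions by chronicity
    bin: annualized percent change, Cohen's d effect sizes, and Pearson
    correlations with confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
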