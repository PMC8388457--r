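Package: pooledPK
Title: Naive Pooled-Sample Pharmacokinetics, NCA and PK/PD Target Attainment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sparse-sample naive pooled pharmacokinetic studies:
    ingestion and validation of sparse concentration-time tables, naive
    pooling with per-time summaries, noncompartmental analysis (Cmax/Tmax,
    log-linear terminal slope, trapezoidal AUC/AUMC, mean residence time),
    one-compartment first-order absorption model fitting, PK/PD ratio
    assessment against MIC breakpoints, Monte Carlo probability of target
    attainment over an MIC dilution grid, and a synthetic sparse-sampling
    data generator for end-to-end validation of the pipeline. Includes the
    pooled feline enrofloxacin-alginate bead dataset as a worked fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
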