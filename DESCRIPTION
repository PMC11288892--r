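Package: thermolip
Title: Thermal Proteome Stability Profiling from Limited Proteolysis Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of in situ protein thermal stability from limited
    proteolysis coupled to mass spectrometry (LiP-MS) over a temperature
    gradient, with companion analyses for thermal proteome profiling (TPP)
    solubility data and differential scanning fluorimetry (DSF) melting
    curves.  Peptide intensity profiles are fitted with exact Gaussian
    process regression, clustered by entropy-regularised fuzzy k-means into
    shape groups, and osmolyte-induced stabilization is quantified as the
    signed area between condition curves over temperature regions where
    their confidence bands do not overlap.  Peptide scores are rolled up to
    residue and protein level by goodness-of-fit weighted quantiles, with
    the false-discovery rate calibrated on replicate-split null
    experiments.  Includes a synthetic-data generator emulating the
    experimental design, two-state DSF melting-curve fits with linear
    baselines, differential-abundance tests (binding, aggregation,
    protease-activity) with moderated t-statistics, and sequence-derived
    protein features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    limma,
    kernlab,
    jsonlite
Config/testthat/edition: 3
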