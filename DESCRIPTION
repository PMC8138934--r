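Package: cafcyto
Title: Boolean Gating and Compositional Statistics for CAF Flow Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for dissecting cancer-associated
    fibroblast (CAF) heterogeneity from multicolour flow cytometry:
    spillover compensation from single-stain bead controls,
    fluorescence-minus-one (FMO) calibrated marker thresholds, a
    hierarchical gating tree (cells, singlets, live, lineage-negative),
    Boolean enumeration of all 63 six-marker subpopulations, per-sample
    composition profiles, and the accompanying statistical layer
    (composition permutation tests, Welch t-tests with two-stage FDR,
    two-way ANOVA with Tukey-Kramer post-tests, linear trend fits, and a
    reference-group batch-effect check). Includes a ground-truth-labelled
    synthetic cytometry generator emulating murine 4T1/4T07 tumour and
    healthy fat-pad samples, plus a minimal FCS 3.1 reader and writer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
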