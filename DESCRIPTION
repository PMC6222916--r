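Package: tftscreen
Title: Tandem Fluorescent Timer Screens for Protein Stability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of high-throughput tandem fluorescent protein timer
    (tFT) colony-array screens that detect changes in protein stability and
    abundance between wild-type and mutant yeast strains. Provides a
    maturation-kinetics model of the mCherry-sfGFP timer, a synthetic screen
    generator with ground truth, colony-level preprocessing (size-based
    exclusion, background correction, log transform, per-plate normalization
    to a reference strain set), a delta-score statistic with an
    empirical-Bayes moderated t-test, threshold-based hit calling with
    hierarchical clustering of delta-score profiles, and the flow-cytometry
    ratio-of-ratios statistic with a Student's t-test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, deSolve
Suggests: testthat (>= 3.0.0), limma, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
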