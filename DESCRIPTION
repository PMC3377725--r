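Package: loopvar
Title: Variance Decomposition for Loop-Design Two-Color Microarray Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene log-linear modelling of interwoven loop-design two-color
    microarray experiments, with LOWESS intensity normalization, three-level
    variance profiling (technical, anatomic, individual), a permutation-based
    D statistic with false-discovery-rate control, averaged fold-change gene
    selection, and local EASE-score functional enrichment. Includes a
    spot-level synthetic-data generator with nested Gaussian variance
    components for calibration and validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
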