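Package: stabref
Title: Reference-Gene Stability Assessment for Quantitative PCR
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selection and validation of qPCR reference (housekeeping) genes.
    Implements geNorm expression-stability ranking (M values with stepwise
    elimination), qBase-style coefficients of variation and normalization
    factors with delta-method error propagation, efficiency-corrected
    relative quantification from quantification cycles (Cq), single-curve
    window-of-linearity amplification-efficiency estimation, threshold-based
    Cq calling, a digital expression-stability screen over read-count
    libraries with library-omission analysis, RNA-quality gates (3':5'
    amplification ratio, spectrophotometric purity), and seeded synthetic-data
    generators for Cq panels, amplification curves and count libraries with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
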