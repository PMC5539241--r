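Package: ceusvv
Title: Quantification of Adventitial Vasa Vasorum from Contrast-Enhanced
    Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify adventitial vasa vasorum neovascularization
    from contrast-enhanced ultrasound (CEUS) cine loops. Extracts
    time-intensity curves from polygonal regions of interest, computes the
    maximal video-intensity enhancement (MVE) and its luminally normalized
    form, and compares graded-atherosclerosis groups with two-sample t
    tests (raw or summary-statistic form), one-way ANOVA, the Friedman
    test, Dunnett's T3 pairwise comparisons based on the studentized
    maximum modulus distribution, and Pearson correlation against
    CD31/VEGF microvessel counts. A synthetic cine-loop and cohort
    generator with known destruction-replenishment kinetics and paired
    histology counts makes every stage of the pipeline verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
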