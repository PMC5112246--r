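Package: twindmr
Title: Paired-Twin Methylation Association and Bump-Hunting DMR Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for epigenome-wide association studies of
    disease-discordant monozygotic twin pairs measured on methylation
    arrays. Provides quality control of beta values (detection p-value
    masking and probe missingness filtering), reference-based estimation
    of blood cell-type proportions with linear removal of composition
    effects, per-CpG co-twin regression of the within-pair methylation
    difference with a disease intercept and exposure slopes, and
    region-level detection of differentially methylated regions by bump
    hunting on smoothed coefficient surfaces with permutation-based
    family-wise error rate, suggestive, empirical and false discovery
    rate inference. Includes a generator of synthetic paired methylation
    data with known spiked effects for calibration and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
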