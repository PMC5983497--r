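Package: biliscreen
Title: Smartphone-Image Screening Analysis for Neonatal Hyperbilirubinemia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for transcutaneous bilirubin screening from
    smartphone skin images of the neonatal glabella. Provides a seeded synthetic
    cohort and image generator calibrated to published channel-intensity/TsB
    correlations, a spectral forward model of skin chromophores and filtered
    camera response, uniform-region selection and RGB intensity extraction with
    quality control, and the screening statistics: Pearson correlation,
    population outlier exclusion, discrimination-limit classification with
    sensitivity and specificity, threshold scans, and stepwise forward
    regression.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
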