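Package: mrpipe
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end two-sample Mendelian randomization from GWAS summary
    statistics: instrument selection at genome-wide significance with
    LD-proxy substitution for variants missing from the outcome data,
    allele harmonization onto a shared effect allele, inverse-variance
    weighted (fixed and multiplicative random-effects), weighted-median and
    MR-Egger estimation, the MR-PRESSO simulation-based outlier test with
    outlier-corrected re-estimation, multivariable MR, instrument-strength
    F-statistics, and a synthetic summary-statistics generator with known
    causal effect and pleiotropy regime for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
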