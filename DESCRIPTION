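Package: epireverse
Title: Quantifying Epigenetic Rejuvenation from DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify partial-reprogramming-induced epigenetic
    rejuvenation from CpG beta-value matrices: elastic-net epigenetic
    clocks with a dual-species relative-age transform, per-CpG
    epigenome-wide association scans with signed Z-statistics and
    rescued/aggravated classification, chromatin-state trimmed-mean
    reversal scoring, TSS-position/CpG-island/chromatin-state enrichment,
    and an optical-dissector stereology estimator. A synthetic
    aging-methylome generator with a known truth table drives the test
    suite, so every stage is exercisable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
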