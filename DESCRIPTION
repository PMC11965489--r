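Package: fieldmark
Title: Epigenetic Field-Defect Signatures from DNA Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and scores DNA-methylation signatures of field
    cancerization in surrogate tissues: a pan-tissue carcinogen-exposure
    signature combined across tissues by geometric-mean rank aggregation,
    reference-based cell-type deconvolution with cross-platform beta-value
    harmonization and bespoke marker-panel construction, a mitotic clock
    over polycomb-group-target promoter CpGs, and a progesterone-receptor
    binding-site methylation score. Includes the sample and probe
    quality-control cascade, principal-component covariate checks,
    tumor-free survival analysis of median-split biomarker strata, and a
    synthetic-data generator emulating bimodal beta-value distributions,
    cell-type mixtures, planted exposure effects, and censored tumor
    latencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
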