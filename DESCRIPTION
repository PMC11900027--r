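Package: schemeDE
Title: Differential Expression and Design Diagnostics for Acute Versus
    Chronic Pesticide Exposure Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for brain RNA-seq experiments that compare
    acute (short-term, high-concentration) and chronic (long-term,
    low-concentration) pesticide exposure in bumble bee microcolonies.
    Provides a synthetic-data generator emulating the blocked study design
    (ten source colonies, seven treatments, negative-binomial counts),
    a transparent negative-binomial Wald differential-expression engine
    with median-of-ratios normalization and colony-aware design,
    simulation-based multi-set overlap enrichment, exposure-scheme
    contrast statistics (amplitude, fold-change proportions, replicate
    variance), replicate-balance and colony-confounding resampling
    diagnostics, Cox proportional-hazards survival comparisons, and
    food-intake and pesticide-dose accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
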