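Package: ibdimmune
Title: Cytokine Network Dynamics, Patient Stratification and TNF-alpha
    Blockade in Inflammatory Bowel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic model of gut mucosal immune regulation in
    inflammatory bowel disease: a 15-variable ordinary differential
    equation system coupling M1/M2 macrophages, Th1/Th2/Th17/Treg cells
    and nine cytokines (IFN-gamma, IL-2, IL-4, IL-6, IL-10, IL-12,
    IL-21, TNF-alpha, TGF-beta). Provides steady-state parameter
    calibration against healthy mucosal mRNA panels, a synthetic
    patient-cohort generator, stratification of patients into four
    Th1/Th2 phenotypes with inverse fitting of per-type rate
    deregulations, in-silico TNF-alpha blockade, and Latin hypercube /
    partial rank correlation coefficient sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
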