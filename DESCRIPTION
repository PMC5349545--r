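Package: biasdx
Title: Diagnostics for Biased Agonism from Concentration-Response Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies GPCR ligand bias from concentration-response curves by
    nine complementary diagnostics: three strategies built on the Black-Leff
    operational model (fixed-Kd transduction ratios, free tau/Kd composites,
    Emax/EC50 ratios), four equi-effective concentration "null method"
    strategies (occupancy ratios at single, common-range and pair-optimized
    response levels, and double-reciprocal slope ratios), and two model-free
    intrinsic-activity methods that test rank-order changes and distances from
    a full-agonist reference trajectory. Includes a parametric-bootstrap null
    band for significance calls, a synthetic panel simulator that reproduces
    the "system bias without ligand bias" negative-control regime, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    MASS,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
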