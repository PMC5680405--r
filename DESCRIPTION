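Package: cedflow
Title: Transport Modelling for Convection-Enhanced Intraputamenal Drug Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models convection-enhanced delivery (CED) of macromolecules such
    as r-metHuGDNF into brain tissue. Solves the spherically symmetric
    convection-diffusion-elimination transport equation around an infusion
    catheter with a finite-volume flux-limited scheme, fits two-compartment
    elimination kinetics to striatal concentration-time data, computes the
    interstitial-fluid bulk-flow clearance estimate, evaluates closed-form
    drug loss during infusion, and summarises distribution volumes, Peclet
    numbers and homogeneity ratios against putamen target geometry. Includes
    a synthetic pharmacokinetic data generator so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
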