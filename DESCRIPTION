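Package: thoriarv
Title: Injury Risk Functions and Assessment Reference Values for the THOR
    Anthropomorphic Test Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Parametric injury-risk functions (Weibull, ordered probit,
    logistic and related dose-response forms) for occupant-injury metrics
    measured on the THOR anthropomorphic test device, with closed-form
    inversion to injury assessment reference values (IARVs) at stated
    acceptable-risk probabilities. Includes signal-level metric calculators
    (HIC-15 sliding-window search, BrIC, average distal forearm speed) for
    multi-channel sled-test time histories, transfer functions between
    surrogate measurement scales (THOR, PMHS, WorldSID, EuroSID, Brinkley
    dynamic response), spaceflight deconditioning factors, landing-mode
    threshold statistics, and an end-to-end pipeline that regenerates the
    full IARV table from printed model coefficients. A synthetic-data module
    generates pulse-shaped test channels with closed-form metric values for
    verification.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
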