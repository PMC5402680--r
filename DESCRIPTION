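Package: neuropk
Title: Pharmacokinetic Modeling of Brain-Derived Blood Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-compartment physiologically-based pharmacokinetic model of
    brain-derived serum biomarkers (S100B monomer and homodimer, GFAP, UCHL-1).
    Brain-to-blood passage is gated by a time-varying blood-brain-barrier
    permeability expressed on a 0-100 radiologic index scale, extracranial
    sources (skin) contribute at a small fixed leak, and elimination is renal
    with a molecular-weight-dependent glomerular sieving coefficient. Provides
    closed-form anthropometric and renal physiology (total blood volume,
    glomerular filtration rate, filtration coefficient, half-life), calibration
    of the maximal brain-to-blood transfer clearance against a post-mannitol
    serum S100B time course, stiff ODE simulation with mass-balance accounting,
    analytic steady states, and scripted scenarios contrasting neonates with
    adults, skin pigmentation levels, sexes, and degrees of kidney failure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
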