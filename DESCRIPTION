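Package: plumeufp
Title: Ultrafine Particle Dynamics and Population Exposure in Dispersing Ship Plumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale model chain for ultrafine particles (UFP) in the
    exhaust plume of a ship near a harbor. Implements a two-stage plume
    dilution model (jet expansion followed by a power-law decay with
    plume-height growth), a fixed-sectional multicomponent aerosol dynamics
    box model (binary homogeneous H2SO4-H2O nucleation with an organic
    variant, analytical-predictor condensation with Kelvin and Raoult
    corrections, Brownian coagulation, dry deposition, entrainment of
    background aerosol), a reduced in-plume gas-phase chemistry scheme
    supplying condensable vapors, and a time-microenvironment-activity
    exposure stage that converts simulated plume concentrations into
    short-term population exposure and excess mortality risk. Includes
    generators for all synthetic inputs (multimodal lognormal exhaust and
    background size distributions, ship-event records, dilution-curve
    samples, population grids).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
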