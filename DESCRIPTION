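Package: fynhyd
Title: Seasonal Plant Hydraulics from Sap Flow, Micrometeorology and
    Optical Vulnerability Curves
Version: 0.1.0
Authors@R:
    person("Jonaskop", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Processing and inference chain for seasonal plant water
    relations in fire-prone mediterranean shrublands. Converts half-hourly
    micrometeorology into vapour pressure deficit, dew-point temperature,
    dew events and calibrated soil moisture; converts heat-ratio sap-flow
    records into heat pulse velocity, sap flux density, transpiration and
    sap-flow-derived canopy stomatal conductance with reference-period
    normalization; builds optical xylem vulnerability curves from drying
    image stacks by frame differencing and event counting, fits the
    sigmoid embolism model to obtain P50, and computes hydraulic safety
    margins and predicted in-situ loss of xylem function; and provides
    seasonal recovery metrics, AIC-based model selection and ANOVA with
    Tukey compact letter displays. Ships synthetic-data generators
    (pulsed-rainfall weather, bucket-model soil moisture, species
    archetypes for ericoid, proteoid and restioid growth forms, and
    drying image stacks) so the full pipeline is testable end to end
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
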