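Package: grassflux
Title: Water Balance, Leaf Energy Balance and Seasonal Inference for a
    C3/C4 Grass Common-Garden Drought Experiment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative drought ecophysiology of C3
    and C4 grasses in a blocked common-garden design. Computes FAO-56
    reference crop evapotranspiration and weekly water deficits under an
    irrigation policy with rainfall-triggered halts; solves an iterative
    leaf energy balance to estimate transpiration from stomatal
    conductance, leaf width and midday microclimate; screens chamber
    gas-exchange records against flux-resolution and leaf-area rules and
    derives intrinsic and instantaneous water-use efficiency; pairs
    predawn and midday leaf water potentials into hydrodynamic gradients
    and whole-plant hydraulic conductance; and fits cell-mean linear mixed
    models with clade-by-month random effects, reporting parametric
    bootstrap confidence intervals and significance flags for
    photosynthetic-type and watering contrasts. A seeded synthetic-field
    generator emulates the seasonal weather statistics and the 12-species,
    4-clade, 2-treatment, 8-block, 6-month design so the whole chain is
    testable end to end without field data.
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
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
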