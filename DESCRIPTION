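Package: pm25burden
Title: Projected Ambient PM2.5 Exposure and Premature Mortality Burden
    Under Combined Climate and Socioeconomic Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects decadal ambient fine-particulate (PM2.5) exposure on a
    half-degree grid by scaling a satellite-derived baseline field with
    relative changes from a multi-model climate ensemble, under two emission
    pathways and two estimation approaches (speciated mass summation and a
    fixed PM2.5/AOD conversion factor).  Converts exposure into attributable
    premature mortality for four diseases with the integrated
    exposure-response (IER) relative-risk model, GDP-adjusted baseline
    mortality and shared-socioeconomic-pathway demographic drivers, across a
    pathway-combination scenario matrix.  Includes counterfactual sensitivity
    analyses isolating demographic, epidemiologic, meteorological and
    policy-cap contributions, a seeded synthetic-data generator emulating the
    statistical structure of the real inputs, and reproducible text-based
    serialization of all artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
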