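Package: sprayscreen
Title: Two-Box Screening Model for Airborne Exposure from Indoor Spraying
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic near-field/far-field (two-box) screening estimates of
    time-weighted average airborne concentrations of non-volatile substances
    released by indoor spray processes, with two refinement routes: aerosol
    dynamics correction factors derived from a well-stirred compartment model of
    droplet evaporation (d-squared law) and gravitational settling, and
    equipment-based airborne release fractions for surface spraying. Includes a
    packaged table of mean correction factors indexed by spraying time, exposure
    time, air exchange rate, solvent vapor pressure class and droplet size
    class, tools to regenerate that table from the aerosol physics, scenario
    input/output in YAML and CSV form, and utilities for comparing modeled with
    measured concentrations by ratio bins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
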