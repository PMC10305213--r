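Package: aeroperf
Title: Aerosol Particle Size Statistics, Cascade Impactor Reduction, and
    Regional Lung Deposition Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in vitro characterization of inhalable aerosol
    formulations: lognormal particle-size distribution fitting and quantile
    math (geometric, volume and aerodynamic diameters with their geometric
    standard deviations), reduction of next-generation cascade impactor (NGI)
    runs to mass median aerodynamic diameter, emitted dose and
    species-specific fine particle fractions, diameter-band prediction of
    regional deposition in human and rat airways (including the obligate
    nose-breather inhalability cutoff of rodents), two-level full factorial
    analysis of spray-drying process parameters, and a seeded synthetic-data
    generator with known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
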