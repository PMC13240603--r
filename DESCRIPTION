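Package: ozoneflux
Title: Stomatal and Non-Stomatal Ozone Deposition from Eddy Covariance Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing pipeline for estimating stomatal and non-stomatal
    ozone dry deposition over a crop canopy from eddy covariance data.
    Computes half-hourly fluxes from high-frequency sonic anemometer and
    gas analyzer records (despiking, double rotation, steady-state and
    integral turbulence quality flags), detects friction velocity
    thresholds and partitions net ecosystem exchange into gross primary
    productivity and ecosystem respiration, resolves the ozone deposition
    velocity into aerodynamic, quasi-laminar and surface resistances,
    estimates stomatal conductance by Penman-Monteith inversion of latent
    heat flux and by windowed fits of the Medlyn conductance model, and
    accumulates flux-based phytotoxic ozone dose (POD6) alongside the
    exposure indices AOT40 and W126. A synthetic big-leaf world generator
    with known parameters provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
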