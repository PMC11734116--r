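Package: chathamrisk
Title: Bayesian-Network Ecological Risk Assessment of Seabed Mining
    Impacts on Benthic Fauna
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete Bayesian-network toolkit for probabilistic ecological
    risk assessment of seabed disturbance, centred on a reconstruction of an
    expert-elicited model of phosphorite-nodule mining impacts on Chatham
    Rise benthic fauna. Implements exact inference by variable elimination
    with a full-joint enumeration oracle, conditional-probability-table
    generation from best/worst-case beta-distribution elicitation with
    weighted parent-state interpolation, deterministic constructors for
    direct removal and the combination of direct and indirect impacts,
    disturbance-scenario queries across spatial domains and time steps, and
    synthetic-data generators (random networks, overdispersed before/after
    benthic core surveys with bootstrap decrease distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
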