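Package: phaeosim
Title: Light- and Nitrogen-Limited Growth, Fatty Acid and EPA Production
    of Phaeodactylum tricornutum in Photobioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates photoautotrophic growth of the diatom Phaeodactylum
    tricornutum under combined light and nitrogen limitation using a
    Droop cell-quota model coupled to Monod light kinetics and a
    Beer-Lambert radiative field for flat-panel and bubble-column
    photobioreactors. Predicts biomass, total fatty acid (TFA) and
    eicosapentaenoic acid (EPA) concentrations from quota-based empirical
    correlations, calibrates kinetic parameters against replicated
    time-series observations by weighted normalized root-mean-square
    error minimization (Nelder-Mead simplex), generates seeded synthetic
    observation sets for testing, and optimizes repeated-batch harvest
    schedules over interval-by-fraction grids, including one-at-a-time
    parameter sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
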