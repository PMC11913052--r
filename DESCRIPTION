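Package: clockkin
Title: Kinetic Modelling and Switchover-Time Inference for the Vitamin C Clock Reaction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mass-action kinetic modelling of the vitamin C / hydrogen peroxide /
    iodine clock reaction. Provides stiff numerical integration of the
    five-species reaction network, matched-asymptotic leading-order solutions
    and closed-form switchover (induction) time formulae in moderate and high
    hydrogen-peroxide regimes, a corner detector for colour-change intensity
    traces, relative least-squares estimation of the iodine fraction and the
    rate-limiting rate constant with BCa bootstrap confidence intervals, and a
    synthetic-data generator for end-to-end parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    boot,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
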