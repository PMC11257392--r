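Package: linsim
Title: Population Dynamics of Bacteriophage Lysis Inhibition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic simulators for the population
    dynamics of T-even bacteriophages that employ lysis inhibition (LIN),
    the delay of host lysis triggered by secondary phage adsorption.
    Implements well-mixed batch models of an r-mutant (rapid-lysis) phage,
    a LIN-capable phage, and their direct competition, with Monod
    nutrient-dependent growth, Erlang-staged latent periods and
    Lotka-Volterra adsorption kinetics; radially symmetric
    reaction-diffusion versions for plaque formation in a soft-agar lawn;
    front-radius metrics for plaque morphology (visible plaque radius,
    zone of infection, phage front positions); parameter sweeps over the
    LIN latency and burst-size fold factors; and an exact event-driven
    (Gillespie) counterpart of the batch models for validation at small
    population sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
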