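Package: blinksim
Title: Two-Stage Dynamical-Systems Simulation of the Attentional Blink
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates rapid serial visual presentation (RSVP) two-target trials
    with a two-stage linear-filter model of attentional resource allocation: a
    Gaussian sensory filter whose output is clipped at unit likelihood, followed
    by a Gamma attentional filter with additive Gaussian "mental noise". Blink
    events are threshold crossings of the attentional load; the model P3b
    amplitude is the resource allocation index scaled by the noise standard
    deviation. Provides exact, extreme-value (Gumbel) and Monte-Carlo blink
    probabilities, detection-versus-lag curves, mental-noise parameter sweeps
    with behavioural consistency checks, least-squares calibration against
    detection curves, synthetic-curve generators for parameter-recovery studies,
    ggplot2 visualisations and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
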