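Package: seatvibe
Title: Seated-Occupant Whole-Body Vibration Modelling and Ride Comfort
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Frequency-domain analysis of a 32-degree-of-freedom
    lumped-parameter model of a seated vehicle occupant under vertical
    base excitation: seat-to-head transmissibility, apparent mass and
    segmental vibration transmissibility; constrained firefly-algorithm
    identification of the 224 biomechanical parameters (segment masses
    and direct/cross-coupled joint stiffness and damping) from target
    response curves; one-factor-at-a-time sensitivity analysis of the
    transmissibility peak; and coupling with a seven-degree-of-freedom
    full-car model for ride-comfort classification against
    exposure-limit curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
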