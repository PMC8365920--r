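Package: gaitenv
Title: Planar Neuromechanical Locomotion Environment with Footstep-Segmented Rewards
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale neuromechanical walking environment: a planar
    seven-segment musculoskeletal model driven by Hill-type muscles, a
    target-velocity-field navigation task with a footstep-segmented reward
    (alive, step and target terms), an agent-facing step/reset interface,
    reflex-style baseline controllers with a derivative-free tuning hook,
    and a harness for generating and scoring trajectory fixtures with
    closed-form expected rewards.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
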