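Package: dyneinflex
Title: Geometry and Mechanics of Microtubule-Bound Dynein Dimers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for side-view measurements of dimeric dynein
    motors bound to microtubules. Converts ring-centre positions and heights
    into stalk angles by trigonometry, classifies superposed and offset
    dimers, and derives mechanical properties of the motor: torsional
    stiffness of the stalk-stalkhead hinge by the equipartition theorem,
    apparent cantilever stiffness, inter-head tension from the dependence of
    stalk angle on stalkhead separation, the stiffness of the elastic
    inter-head linkage, and per-head duty ratios from single-molecule run
    lengths. Includes a Boltzmann mechanical model of dimers on the
    microtubule lattice that generates synthetic particle tables, toy
    micrograph renders and stochastic run lengths, so every stage of the
    pipeline is testable without micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
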