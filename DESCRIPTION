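Package: rbcshape
Title: Axisymmetric Membrane Mechanics of Red Blood Cell Shape Under
    Heterogeneous Active Forces
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Solves the axisymmetric Helfrich-Canham shape equation for a
    closed, reflection-symmetric membrane under spatially heterogeneous,
    oriented force densities that mimic nonmuscle myosin IIA contractility
    on the red blood cell membrane. Provides the Evans-Fung parametric
    biconcave reference geometry and its measures, a boundary-value solver
    with parameter continuation from the zero-force sphere, shape-error
    metrics against the reference profile, dimple/rim partitioning and
    force-per-volume ratios, parameter sweeps over force density, membrane
    tension and force orientation, and synthetic-data generators for noisy
    reference profiles and three-dimensional myosin puncta point patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
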