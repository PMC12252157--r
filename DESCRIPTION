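Package: printfid
Title: Print-Fidelity Optimization for Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing extrusion-based 3D bioprinting of
    shear-thinning hydrogel inks. Implements an analytic power-law
    (Ostwald-de Waele) nozzle-flow model that predicts volumetric flow,
    pressure drop and deposited filament diameter from rheology and process
    parameters; image-based print-fidelity scoring (structural similarity,
    dimensional similarity and their aggregate, plus caliper-style
    percentage-error similarity); a seeded convolutional binary classifier
    that labels printed-mesh images High/Low fidelity and maps the best
    print back to its process parameters; full-factorial design-of-
    experiments construction with centered-coded polynomial regression,
    alpha-level term pruning, main-effects and response-surface evaluation;
    and synthetic-data generators (rheology curves, grid-scaffold images
    with ground truth, factorial response tables) so the whole pipeline is
    exercisable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
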