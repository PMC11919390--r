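Package: condensateADSA
Title: Axisymmetric Drop-Shape Analysis of Sessile Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures contact angles of sessile biomolecular condensates from
    three-dimensional confocal stacks by axisymmetric drop-shape analysis:
    segmentation of two-channel z-stacks into per-condensate axisymmetric
    profiles, Young-Laplace fitting of those profiles with quality and size
    filters, and correction of the axial stretch introduced by imaging aqueous
    samples through an oil-immersion objective. Includes a synthetic-data
    generator for sessile-drop stacks, a deterministic ray tracer and
    point-spread-function convolution engine to simulate the optical
    aberrations that motivate the corrections, and Flory-Huggins binodal
    fitting of cloud-point data to quantify the degree of phase separation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
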