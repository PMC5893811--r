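Package: laastasis
Title: Hemodynamic Stasis Analysis in Parametric Left Atrial Appendage Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics of the left atrium and left
    atrial appendage (LAA). Generates parametric two-dimensional anatomies for
    the four canonical LAA morphologies (chicken wing, cactus, windsock,
    cauliflower), meshes them with unstructured triangles, imposes pulsatile
    mitral-outlet waveforms for normal sinus rhythm and atrial fibrillation,
    and solves transient incompressible laminar Navier-Stokes flow with a
    finite-element projection scheme. A passive virtual contrast agent is
    washed out over several cardiac cycles to quantify blood stasis, together
    with shear-strain-rate fields, ostium-to-tip centerline profiles and
    appendage-normalized volume integrals used to rank thrombosis risk across
    morphologies and rhythm conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
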