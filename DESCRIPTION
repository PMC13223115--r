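Package: mdpcarto
Title: Cartography of Cell Behaviours in the Embryonic Mandibular Prominence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies three-dimensional cell behaviours in early craniofacial
    mesenchyme from spindle-pole annotations, nuclear morphology and tissue
    surface meshes. Implements axial (orientation-without-direction) circular
    statistics with angle doubling (Kuiper uniformity and two-sample Watson U2
    tests), neighbourhood mitotic alignment scores in a 200 micrometre ball,
    mediolateral segment analysis, local mitotic index, CellProfiler-style
    nuclear shape features with PCA, ordinary Procrustes superimposition of
    landmark configurations with thin-plate-spline atlas morphing and signed
    closest-point surface distance maps, nested isomorphic shells, ray-cast
    positional mitotic orientation, and a seeded synthetic-tissue generator
    that emulates the mediolateral gradients of division alignment, mitotic
    rate and nuclear shape variance the analysis is designed to recover.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
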