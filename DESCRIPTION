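Package: rfam
Title: Recurrent Form Analysis Models of Multipoint Texture Selectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools to study how early visual cortex could compute selectivity
    for multipoint spatial correlations. Synthesizes maximum-entropy glider
    textures (multipoint spatial correlation textures, MSCT) and moving- and
    oriented-noise probe stimuli; generates surrogate V1/V2 spiking responses
    with class-selective gains and transient/sustained dynamics; fits a
    feedforward linear-nonlinear baseline via spike-triggered moments and
    maximally informative (iSTAC) subspaces; trains a two-stage locally
    recurrent (Elman-type) network by backpropagation through time to
    reproduce texture-evoked response dynamics; and probes trained networks
    with texture, orientation, translation and rotation stimuli to measure
    emergent tuning indices, response-dynamics embeddings, and
    ridge-regression similarity between model layers and neural populations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
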