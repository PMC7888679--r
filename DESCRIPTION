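Package: memsearch
Title: Target-Search Kinetics of Membrane-Integrated DNA-Binding Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how a membrane-integrated transcription factor
    finds its chromosomal binding site by two-dimensional diffusion in the
    membrane coupled to conformational fluctuations of the DNA. Provides the
    hypoexponential first-passage-time model of a reversible two-step capture
    process (densities, distribution functions, moments) and weighted
    least-squares fitting of single-cell response curves with full-covariance
    error propagation; closed-form mean-encounter-time estimates on spherical
    membranes and in confined volumes; a kinetic Monte Carlo lattice
    simulation of a confined phantom bead-spring polymer coupled to a
    surface-diffusing protein; ensemble mean-square-displacement analysis of
    chromosomal locus trajectories with Rouse-model conversion to a bead
    diffusion constant; fluorescent-spot detection in segmented bacterial
    cells; and synthetic-data generators with known ground truth for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    mgcv,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
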