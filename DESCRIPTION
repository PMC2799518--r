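Package: epidermabm
Title: Multiscale Agent-Based Simulation of Human Epidermis with TGF-beta1 Signalling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows a stratified virtual human epidermis from seeded keratinocyte
    stem cells and simulates wounding and re-epithelialisation. Couples three
    layers in 30-minute iterations: cellular agent rules (division with contact
    and TGF-beta1 inhibition, a stem to transit-amplifying to committed to
    corneocyte differentiation cascade, contact-preserving active migration),
    a per-cell TGF-beta1 subsystem (promoter activity, capped transcription and
    translation, and a ligand-receptor trafficking network integrated with an
    adaptive Runge-Kutta scheme), and a tile lattice of extracellular matrix
    that stores latent TGF-beta1 and remodels from provisional matrix through
    secondary matrix to basement membrane. An overlapping-spheres mechanics
    solver resolves cell overlap, bond attraction, and wall constraints each
    iteration. Includes a wound operator, census and snapshot output, a healing
    driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
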