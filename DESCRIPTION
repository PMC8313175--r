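Package: resdisc
Title: Residual Strain in the Intervertebral Disc by Osmotic Swelling and
    Multigenerational Annulus Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-static continuum simulator of the intervertebral disc as an
    osmotically swelling, fiber-reinforced, biphasic-at-equilibrium tissue.
    Implements the Holmes-Mow extrafibrillar matrix, strain-dependent
    permeability, Donnan equilibrium swelling pressure, and toe-region
    power-law annulus fibers on parameterized hexahedral meshes of a human
    disc and a bovine caudal disc cylinder. Annulus fiber pre-strain is
    established by multigenerational deposition: fiber families are assigned
    reference configurations recorded at prescribed twist states so the
    neutral disc carries fiber residual stress in addition to swelling
    residual stress. Includes the radial-incision (opening gap) residual
    strain experiment, axial/torsion/bending loading protocols on rigid
    platens, a one-dimensional transient biphasic consolidation engine, and
    validation metrics (normalized mean square error against experimental
    mean and confidence-interval curves, disc height, lateral bulge, opening
    gap, anatomic-axis tensor transforms).
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
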