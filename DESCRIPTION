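Package: memxrd
Title: Analysis of X-Ray Diffraction from Oriented Multilamellar Lipid Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to localize small peptides and additives in stacked lipid
    bilayers from specular X-ray reflectivity and in-plane diffraction.
    Implements Gaussian Bragg-peak fitting with Lorentz correction, sign
    (phase) assignment by the swelling method, one-dimensional Fourier
    synthesis of electron-density profiles on an absolute electron scale,
    mirrored-Gaussian decomposition of difference densities into molecular
    populations, projection of atomic structures into Gaussian-broadened
    one-dimensional densities with rigid-body pose fitting, in-plane lattice
    analysis (hexagonal chain packing, oblique two-dimensional lattices),
    and a seeded forward simulator that generates ground-truth test data
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
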