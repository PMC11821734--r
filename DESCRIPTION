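Package: gagring
Title: Glycosaminoglycan Donnan Swelling and Residual Stress in Arterial Rings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the contribution of glycosaminoglycan (GAG) fixed charge
    density to circumferential residual stress in arterial rings. Converts
    mural sulfated-GAG profiles to fixed charge densities, evaluates Donnan
    osmotic pressure in a Holmes-Mow porous solid matrix, fits one- and
    two-layer membrane constitutive parameters to planar biaxial data, and
    solves the swelling equilibrium of a quarter aortic ring with 20-node
    hexahedral finite elements to predict the opening angle. Includes a
    reduced opened-sector oracle, synthetic data generators, reference
    porcine aorta datasets, and evaluation reporting against experimental
    GAG-depletion opening angles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
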