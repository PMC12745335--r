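Package: aortagrowth
Title: Structural Wall Stress and Growth-Rate Mapping for Dissected Aortas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline linking acute structural wall stress to
    aortic growth in type B aortic dissection. Generates synthetic dissected
    aorta geometries (outer wall, dissection flap, tears, mural thrombus),
    computes lumen pressures and wall shear stress with a calibrated
    reduced-order resistive network, solves forward-penalty linear
    elasticity on a conforming hexahedral wall mesh to obtain maximum
    principal wall stress, maps three-dimensional growth rates between
    baseline and follow-up geometries by rigid (ICP) plus nonrigid
    (varifold-kernel) surface registration, and fits random-slope linear
    mixed-effects models relating regional stress, wall shear stress,
    pressure and thrombus presence to regional growth rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
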