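Package: carotidflow
Title: Reduced-Order Hemodynamics and Plaque Concordance for Bent,
    Bifurcating Carotid Arterial Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced-order (algebraic) hemodynamic model of blood velocity
    and wall drag shear stress along a bent, bifurcating arterial tree.
    Velocity attenuates by cos(theta) at each bend, drag stress scales as the
    remaining velocity fraction over the cross-sectional area, and flow splits
    at bifurcations in the ratio of daughter areas.  Ships a fifteen-section
    cadaveric carotid fixture (radii, bend angles, plaque thickness), tools to
    recompute its published per-section stress indices with discrepancy flags,
    a predicted-risk versus observed-plaque concordance analysis (exact or
    Monte-Carlo permutation rank test), and a synthetic tree-and-plaque
    generator with hinge-model parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
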