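Package: bbpls
Title: Multimodal Brain-Behavior Partial Least Squares Correlation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links dimensions of childhood psychopathology to multimodal
    brain features with partial least squares (PLS) correlation: singular
    value decomposition of the item-by-feature cross-covariance, site-aware
    permutation and bootstrap inference with network-block averaging,
    diffusion-map embedding of connectivity gradients, spin permutation
    tests for spatially autocorrelated cortical maps, and matched
    discovery/replication generalizability analyses. Ships a synthetic
    multimodal cohort generator with planted low-rank latent structure,
    site batch effects, and a spherical parcellation, so that every stage
    can be exercised and validated end-to-end against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tools,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
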