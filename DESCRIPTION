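Package: framenet
Title: Stable-Edge Frame Networks from Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies "frame networks" - the small set of functional
    connections whose within-subject strength ranking is most stable across
    a cohort, measured by the coefficient of variation of edge ranks - from
    region-by-region Fisher-z connectivity matrices. Includes a latent-factor
    cohort simulator with realistic covariates and symptom scores,
    covariate-adjusted edgewise group comparison with false-discovery-rate
    control, symptom-edge correlation analysis, and a nested
    leave-one-out-cross-validated linear support vector classifier with
    permutation testing, plus worked-example checks against published
    reference networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
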