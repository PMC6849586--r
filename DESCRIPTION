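Package: burstshift
Title: Nested Early-Burst and Rate-Shift Models of Trait Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood fitting and comparison of phylogenetic models in
    which a background Brownian-motion process switches to an early-burst,
    rate-shifted, or Ornstein-Uhlenbeck process inside one nested monophyletic
    clade. Provides variance-covariance transformations for seven models of
    continuous-trait evolution, AICc-based shift-node scanning with
    simulation-calibrated control of the null selection rate, birth-death tree
    and multivariate-normal trait simulators for power studies, and the
    node-height test of early-burst patterns from phylogenetic independent
    contrasts (ordinary, robust, and outlier-trimmed).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
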