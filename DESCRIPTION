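Package: orchardRF
Title: Individual-Tree Climate Response Functions from Pedigreed Seed-Orchard Progeny
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Combines pedigree-based individual genetic evaluation (bivariate
    animal model fitted by restricted maximum likelihood, breeding values by
    Henderson's mixed-model equations) with climate response functions, so
    that intra-population adaptive variation in tree growth can be mapped
    along a climatic gradient. Includes a seed-orchard progeny simulator
    (open pollination with pollen contamination, half/full-sib structure,
    two correlated traits), the numerator relationship matrix by the tabular
    method, random-forest style ranking of collinear climate variables, and
    population- and family-level quadratic, linear and Gaussian response
    curves with AIC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
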