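Package: crossfeed
Title: Stability and Structural Stability of Consumer-Producer-Resource
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling microbial communities as consumers of abiotic
    resources with optional crossfeeding (production of resources by
    consumers). Simulates the coupled consumer-resource ordinary differential
    equations, solves forward and inverse equilibrium problems, assembles the
    community Jacobian and its eigenvalue spectrum, evaluates local-stability
    criteria (including the specialist gamma-mapping, a sufficient production
    bound, a Gershgorin reciprocity criterion, invasion fitness and a
    positive-definiteness certificate), and estimates structural-stability
    (feasibility-domain) volumes by closed form and Monte Carlo. Includes
    ensemble generators for pooled Jacobian spectra and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
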