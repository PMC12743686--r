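Package: traumanet
Title: Trauma Network Design Under Demand Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage stochastic maximal-covering facility-location models
    for siting trauma care centers and aeromedical depots under scenario-based
    demand uncertainty. Builds the deterministic-equivalent mixed-integer
    program, applies benchmark/construction/improvement network-design
    variants, solves it exactly with a structure-exploiting branch-and-bound,
    and reports per-county coverage. Includes a seeded synthetic service-area
    generator and a brute-force optimality oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
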