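Package: enchainr
Title: Growth-Fragmentation Dynamics of IgA-Enchained Bacterial Chains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the population dynamics of linear bacterial chains formed
    by secretory-IgA enchained growth in the gut lumen. Builds the truncated
    linear operators for five model variants (fixed replication rate, escape
    upon replication, fixed replication time, subchain escape after breaking,
    and force-dependent link breaking), extracts long-time growth rates and
    stationary chain-length distributions from their dominant eigenpairs,
    provides the closed-form approximations for these distributions, an exact
    event-driven stochastic simulator of the same rules, and maximum-likelihood
    fitting of the replication-to-breaking-rate ratio to observed chain-length
    histograms with profile-likelihood confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
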