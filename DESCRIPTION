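Package: retroclock
Title: Time-Dependent-Rate Dating and Codivergence Analysis for Retroviruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the age of retroviral lineages and
    endogenous retroviruses (ERVs). Implements power-law
    time-dependent-rate (TDRP) dating calibrated on host co-speciation,
    with posterior propagation over Bayesian tree samples and highest
    posterior density summaries; LTR-divergence dating of endogenous
    elements under the Tamura-Nei (TN93) substitution model; an exact
    event-based co-speciation maximisation with a random tip mapping
    permutation test; detection of paired long terminal repeats and
    target-site duplications in contigs; and seeded synthetic-data
    generators so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
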