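Package: moalink
Title: Synthesis and Enrichment Testing of Links Between Behavior
    Change Techniques and Mechanisms of Action
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for synthesising coded corpora of author-described
    links between behavior change techniques (BCTTv1) and mechanisms of
    action (26 theoretical constructs drawn from the Theoretical Domains
    Framework and frequent theory constructs). Reads and validates the
    three-table corpus schema (source, BCT, link), deduplicates link
    statements to one per article, builds the BCT-by-MoA link-frequency
    matrix with marginals, tests each cell against a marginal-product
    binomial null with a one-tailed exact test, summarises and exports
    the significant link set, and renders a clustered p-value heat map.
    Includes a seeded synthetic-corpus generator with a ground-truth
    link-propensity matrix for calibration and power studies, and
    inter-coder agreement statistics (percent agreement and
    prevalence-and-bias-adjusted kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
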