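Package: seedfate
Title: Seed Bank Survival Accounting from Buried Seed Packet Experiments
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying seed bank survival from in-situ buried
    seed packet experiments. Seeds recovered from packets are partitioned
    into expended (germinated or decayed), retained, and assayed pools;
    seed bank survival is estimated as the product of the retained
    proportion and the staining (viability) rate, aggregated across
    experimental strata, and compared across species, microhabitats and
    burial durations with rank-based tests and quasibinomial logit
    regression with Type III deviance tests. A multistate seed-fate
    simulator generates packet tables with the statistical structure the
    analysis assumes, supporting calibration, parameter-recovery studies
    and fully reproducible pipelines, including proportionally accurate
    Sankey flow tables for visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
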