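Package: contrastmine
Title: Deep Exploratory Contrast Mining for Subgroup Cohort Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers and prioritizes pairs of contrasted patient subgroups
    from categorical genotype/phenotype tables. Subgroup pairs are defined by
    positionally matched category conjunctions over population variables and
    are characterized by contrast patterns: measurement itemsets whose support
    differs markedly between the two sides of a pair. The search engine
    combines sequential floating selection of population variables with a
    multi-path "guided cascading shotgun" expansion that keeps the most
    promising candidate paths at every layer and prunes duplicate subgroups.
    Candidate pairs are scored with a g-index-style J value over
    tanh-normalized growth rates and re-ranked with a Bayesian-average size
    modification. A planted-cohort benchmark generator and coverage metrics
    make the whole pipeline testable without access-restricted clinical data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
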