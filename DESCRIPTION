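Package: epicomp
Title: Fitness-Landscape Prediction of Compensatory Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Classifies gene-pair genetic interactions from double-mutant
    fitness data by a k-standard-deviation significance rule, projects
    loss-of-function mutations observed in experimentally evolved deletion
    lines onto the resulting fitness landscape, tests observed beneficial
    frequencies with exact binomial statistics, and estimates the
    beneficial fraction of nonsense mutations from an opportunity-normalized
    nonsense-to-synonymous rate ratio. Ships synthetic-data generators with
    planted ground truth so every pipeline stage can be validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
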