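Package: gainscan
Title: Expression-Based Chromosome-Gain Inference and Downstream Survival,
    Translational-Regulation and Drug-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Re-usable implementation of an analysis chain that links
    chromosome-arm copy-number gain, inferred from bulk expression via
    single-sample gene-set enrichment scoring and two-group hierarchical
    clustering, to patient overall survival (Kaplan-Meier estimation,
    Mantel-Haenszel log-rank testing, and a genome-wide survival batch
    screen with multiple-testing control); preranked gene-set enrichment
    with a permutation null and multi-analysis intersection; integration
    of paired knockdown proteome/transcriptome profiles to isolate
    translationally regulated proteins and prioritize candidates; and
    four-parameter logistic dose-response fitting with IC50-shift ranking.
    Seeded synthetic-data generators with planted ground truth emulate the
    cohort, knockdown and drug-screen inputs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    fgsea,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
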