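Package: ifliver
Title: Expression-Pattern Analysis of Intermittent-Fasting Liver Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for four-group liver microarray experiments
    contrasting ad libitum feeding (AL), chronic restriction (CR) and
    intermittent fasting sampled on a fed day (F2) and a fasting day (SK).
    Provides probe-to-probe-set summarization with array quality control,
    per-gene linear models with empirical-Bayes moderated t-statistics for all
    pairwise treatment contrasts, a joint significance/fold-change inclusion
    filter, two-way hierarchical clustering with a fixed-k cut, a taxonomy of
    switching and chronic expression patterns, local hypergeometric pathway
    over-representation with a shared/unique gene partition, and
    Bonferroni-controlled correlation of cluster or gene expression with
    physiological traits. A synthetic-data generator plants every pattern
    class with known effect sizes so the whole pipeline can be validated
    against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
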