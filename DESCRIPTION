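Package: pangmix
Title: Population Structure-Aware Association Testing for Microbial Pangenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Metagenome-wide association testing that links host traits to
    within-species genetic variation of microbiome species. From a binary
    sample-by-gene presence/absence matrix, pangmix builds a species-level
    genetic relatedness matrix (one minus normalized Manhattan distance),
    fits a generalized linear mixed model by penalized quasi-likelihood with
    AI-REML variance-component updates, tests whether strain-level population
    structure associates with the trait via a permutation test on the random
    effects, and tests each gene family with a score test whose tails are
    corrected by a saddlepoint approximation for unbalanced case/control
    designs. Multiple testing is handled with an empirically fitted null and
    local false discovery rates. Includes a synthetic-data suite emulating
    strain-structured pangenomes for calibration and power studies, and a
    relative-abundance baseline test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
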