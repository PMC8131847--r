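Package: switchcor
Title: Differential Co-Expression Networks and Switching Gene-Pair Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-condition differential co-expression analysis for
    gene-by-sample expression matrices: weighted co-expression network
    construction with scale-free soft-threshold selection, topological
    overlap modules and eigengenes, Fisher z-difference testing of
    per-condition correlations with local false discovery rate control,
    detection of "switching" gene pairs whose correlation flips sign
    between conditions intersected with differential expression,
    eigen-molecule module networks, hypergeometric gene-set enrichment,
    and a minimum-p expression-cutoff Kaplan-Meier/log-rank survival
    scan. Includes a synthetic-data generator with planted modules,
    switching pairs, differential expression and survival effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
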