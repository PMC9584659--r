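Package: hfia
Title: Hybrid Fisher-Filter and Immune-Algorithm Feature Selection for
    High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects minimal, high-accuracy feature subsets from labelled
    high-dimensional expression matrices (microarray or single-cell style,
    thousands of features, tens of samples). A Fisher-score filter first
    reduces the feature space to a fixed-size candidate set; an improved
    clonal-selection immune algorithm then searches that set using
    Cauchy-distributed population initialisation, a k-nearest-neighbour
    cross-validation fitness that trades classification error against
    subset size, conditional lethal mutation driven by an adaptive
    acceleration factor, and an incremental population update with a
    diversity factor. Includes a synthetic-data generator with planted
    informative features, an ablation harness, tidy() and glance()
    accessors, ggplot2 plots, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    class,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
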