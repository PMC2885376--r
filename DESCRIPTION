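Package: miract
Title: Inferring MicroRNA Activity from Gene Expression by Co-Inertia Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Couples a genes-by-samples expression matrix with genes-by-miRNA
    predicted target-site count tables to infer which microRNAs are active in
    a condition. Both tables are decomposed by non-symmetric correspondence
    analysis, the expression side optionally condensed to group centroids
    (between-group analysis), and the pair linked by co-inertia analysis so
    that miRNAs plotted opposite a sample group are inferred active there
    (their targets being down-regulated). Per prediction program the
    supervised axis yields a ranked miRNA list; lists are merged by a top-K
    consensus rule with average ranks. Includes a synthetic-data generator
    with planted miRNA activity for validation, tidy() and glance() methods,
    ggplot2 autoplots and a small command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    patchwork,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
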