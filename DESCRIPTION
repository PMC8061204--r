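Package: coordpc
Title: Whole-Transcriptome Expression Coordination Analysis with the
    Composite Correlation Index (Pc)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how the co-expression structure of a transcriptome is
    retained, lost, or inverted between two conditions (for example young and
    old animals). For every gene it computes the vector of Pearson correlations
    with all other genes within each condition, then summarises the change as
    the composite correlation index Pc, the Pearson correlation between the two
    correlation vectors. Includes CPM normalisation of RNA-seq counts, a
    memory-bounded blocked correlation engine, cohort comparison with
    size-normalised Mann-Whitney tests and quartile reports, top-k rankings and
    gene-list export, ggplot2 visualisations, and a seeded synthetic-count
    generator with modular correlation structure and controllable coordination
    inversion for end-to-end validation.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
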