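Package: corrshift
Title: Differential Gene-Pair Correlation Analysis for Diagnostic Panel
    Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for discovering candidate diagnostic biomarkers from
    two-group bulk RNA-seq abundance matrices by combining differential
    expression with differential gene-pair correlation. The pipeline
    identifies differentially expressed genes between case and control
    groups, scores pathway overrepresentation with a one-sided
    hypergeometric test against user-supplied GMT gene sets, computes
    per-pathway Pearson correlation matrices separately in each group,
    selects gene pairs whose correlation shifts beyond a cutoff
    (|delta CC| >= 0.70 by default), and assembles a panel from the
    top up- and downregulated genes plus the correlation-shifted genes.
    A synthetic-data generator with planted fold changes and planted
    correlation structure makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
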