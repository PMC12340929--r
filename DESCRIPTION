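Package: cortexpheno
Title: Multi-Modal Phenotyping Statistics for Mouse Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and estimators for multi-modal phenotyping of mouse
    cortex. Implements pseudobulk differential expression with a
    log-CPM/Welch-t engine, the cell-type DE-burden statistic with exact and
    Monte-Carlo permutation tests, expression-matched module scoring and
    differential co-expression-module testing against the grey (unassigned)
    module, X/Y-marker sex demultiplexing with pool-design genotype
    assignment and cell-type proportion models, calcium transient detection
    from dF/F traces with depth-binned pairwise correlation analysis and
    dendritic-spine turnover metrics, hypnogram-based sleep-architecture
    statistics, and design-based stereology (Cavalieri, optical
    fractionator, nucleator). Every stage has a matching synthetic-data
    generator with recorded ground truth so the full pipeline is testable
    without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    arrow,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
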