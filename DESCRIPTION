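Package: phenogi
Title: Phenomic Quantification of Drug-Gene Interaction from Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for quantitative high-throughput cell array
    phenotyping (Q-HTCP) of a mutant library under a drug dose series in two
    metabolic contexts. Fits logistic growth curves to culture image-intensity
    time series to obtain cell proliferation parameters (carrying capacity K,
    maximum specific rate r, time to half-carrying-capacity L, and AUC),
    scores per-gene drug interaction by dose regression of reference-adjusted
    parameters standardized against replicate reference cultures, clusters
    interaction profiles by recursive expectation-maximization Gaussian
    mixtures, summarizes Gene Ontology terms by hypergeometric enrichment and
    by term averaging (GTA), and predicts human genes whose expression in
    drug-sensitive cancer cell lines matches yeast enhancer/suppressor
    evidence through homology. Includes a synthetic-data generator that
    emulates the statistical structure of all pipeline inputs so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
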