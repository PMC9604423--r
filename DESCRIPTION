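Package: methRecomb
Title: DNA Methylation Context Landscapes and Prediction of Meiotic
    Recombination Rates
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links per-cytosine DNA methylation calls in the CG, CHG and CHH
    sequence contexts to meiotic recombination landscapes in plant genomes.
    Counts highly methylated cytosines in fixed genomic windows, intersects
    them with gene, transposon and retrotransposon annotations, computes
    centromere-stratified per-chromosome Pearson correlations after
    exponential smoothing, attributes predictive weight to each context by
    exact coalition-enumeration Shapley values, and predicts recombination
    rates across datasets with an extremely-randomized-trees regressor.
    Includes a calibrated synthetic-data generator emulating a rice-like
    genome so the whole pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    data.table,
    ranger,
    randomForest,
    xgboost,
    caret,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Epigenetics, DNAMethylation, FunctionalGenomics, Regression,
    Software
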