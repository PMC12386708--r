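Package: sraselect
Title: Supervised Rank Aggregation Feature Selection for High-Dimensional SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for ultra-high-dimensional SNP genotype panels
    ahead of multi-class (e.g. breed) classification. Implements three
    strategies: linkage-disequilibrium tagSNP pruning; one-dimensional
    supervised rank aggregation (ensembles of multinomial logistic
    regressions on random SNP subsets, aggregated through a mixed linear
    model solved by preconditioned conjugate gradients, followed by
    one-dimensional 2-means clustering of the SNP effect solutions); and
    multidimensional supervised rank aggregation (several independent
    ensemble repeats collapsed into a weighted dense score matrix and
    clustered by multidimensional 2-means). A compact one-dimensional
    convolutional neural network with focal loss, stratified
    cross-validation and macro F1 / macro AUC metrics evaluates the selected
    SNP sets, and a Balding-Nichols genotype simulator with haplotype-block
    linkage disequilibrium and planted class-discriminative SNPs makes the
    whole pipeline testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
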