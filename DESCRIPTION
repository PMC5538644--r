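Package: cohet
Title: Ancestry Dissection and Gene Co-Heterozygosity Networks for Admixed
    Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting the ancestry composition of admixed
    populations from dense SNP genotypes using heterozygosity and
    Hardy-Weinberg equilibrium statistics.  Implements a six-stage pipeline:
    SNP-to-gene mapping with a 1 kb window, principal component analysis of
    standardized genotypes, two-component Normal mixture modelling of PC1
    SNP loadings to assign per-SNP and per-gene posterior membership to two
    ancestral components, per-breed percentage-heterozygosity and
    Hardy-Weinberg screening with hierarchical clustering of breeds,
    permutation and hypergeometric tests of gene-set ancestry skew, and
    inference of a gene co-heterozygosity network with the partial
    correlation and information theory (PCIT) algorithm, including
    scale-free degree diagnostics and a fertility-gene trio coverage
    search.  A Balding-Nichols simulator of admixed genotype panels with
    gene-block structure makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    ape,
    IRanges,
    S4Vectors,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
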