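Package: gwsel
Title: Genomewide Selection Prediction and Postdiction for Clonal Fruit Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating genomewide (genomic) selection in a clonally
    propagated fruit breeding program. Includes a family-structured breeding
    population simulator (pedigreed genotypes under Haldane recombination and
    multi-year phenotypes with controlled variance partitions), across-year
    phenotype adjustment by mixed-model BLUPs, SNP quality control with
    per-chromosome redundancy pruning, an RR-BLUP genomewide prediction engine
    with REML variance estimation, the standard training/test cross-validation
    schemes (random fractions, leave-one-family-out, within-family delete-one,
    family-size subsets, SNPs-per-chromosome subsampling), fixed-effect
    modelling of large-effect QTL markers, and retrospective independent-culling
    comparison of phenotypic versus genomewide selection decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
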