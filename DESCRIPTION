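Package: repgblup
Title: Repeatability GBLUP for Genome-Enabled Prediction in Biparental
    Fruit-Tree Progenies
Version: 0.1.0
Authors@R:
    person("repgblup", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for genome-enabled prediction of repeated-record fruit
    traits in biparental (F1) progenies: genotype quality control and
    import/export, a genotype-masking imputation-accuracy benchmark with
    pluggable imputers, allele-frequency-standardized genomic relationship
    matrices with principal-coordinate and neighbor-joining views of
    population structure, a repeatability GBLUP mixed model (additive
    genetic + permanent environment + year) fitted by AI/EM-REML or Gibbs
    sampling, heritability and repeatability estimation, and k-fold
    cross-validated predictive ability with GEBV accuracy. Includes a
    simulator of F1 crosses with recombination under the Haldane map
    function so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
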