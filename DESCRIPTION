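Package: grburden
Title: Population Comparison of Polygenic Risk Burden from VCF Genotypes
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes per-individual weighted genetic risk burden (GRB)
    scores for a panel of trait-lowering variants from VCF genotypes,
    and performs stratified population comparisons: group mean contrasts
    with Welch t-tests, risk-allele frequency tables, rare- and
    fixed-allele classification, allele frequency spectrum summaries,
    and an exact-binomial test for an excess of rare risk alleles
    (purifying selection). Includes a Balding-Nichols multi-population
    cohort simulator (VCF + sample panel + annotation table with known
    ground truth) so the full pipeline is testable without external
    downloads, and a command-line driver for end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    optparse,
    jsonlite,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
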