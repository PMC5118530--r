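Package: famvc
Title: Family-Based Variance-Components Association Analysis of Candidate Loci
Version: 0.1.0
Authors@R: c(
    person("famvc", "Developers", email = "famvc-dev@example.org",
           role = c("aut", "cre")))
Description: Simulation and analysis toolkit for family-based genetic
    association studies of type-2-diabetes-related quantitative and binary
    traits in extended pedigrees. Provides pedigree and block-LD genotype
    simulation with liability-threshold binary traits, theoretical (pedigree)
    and empirical (dosage-based) kinship matrices, a maximum-likelihood
    variance-components engine with an eigendecomposition fast path,
    measured-genotype association scans with rank-based inverse-normal
    transformation and Li-Ji effective-test multiple-testing correction,
    a cross-trait probability score, genotype-by-age and genotype-by-sex
    interaction tests with subgroup fits, exhaustive BIC-scored model
    selection over SNP subsets (BQTN), and a locus-level variance-component
    gene burden test with half-chi-square mixture-null inference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
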