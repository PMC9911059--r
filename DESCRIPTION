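Package: tetraGP
Title: Bayesian Multi-Environment and Multi-Trait Genomic Prediction for
    Autotetraploid Crops
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction for polysomic tetraploid crops such as
    potato. Builds a full-tetrasomic genomic relationship matrix from SNP
    allele dosages (0-4) using a five-class genotype indicator coding that
    captures additive and nonadditive effects, and fits four Bayesian
    genome-based prediction models with genotype-by-environment
    interaction: a single-trait reaction-norm model with a Hadamard
    interaction kernel, two single-trait models with Kronecker-structured
    environmental covariances, and a multitrait multi-environment
    matrix-variate model. Includes reproducible cross-validation schemes
    for sparse-testing scenarios (whole-environment and 70 percent
    cultivar masking, with all-trait or per-trait masking), Pearson
    correlation and prediction mean squared error scoring, and a synthetic
    multi-environment trial generator with known simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
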