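Package: phenobridge
Title: Phenotype-Conditioned Diffusion Modelling and State Bridging for
    Gene Expression Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a phenotype-conditioned denoising diffusion model on bulk
    gene expression matrices and uses it for two tasks: augmenting expression
    data by sampling from noise, and perturbing samples from one phenotype
    state to another (e.g. tumour to normal) along the deterministic
    implicit-diffusion ODE bridge. Includes the surrounding screening
    pipeline: log2/min-max preprocessing, silhouette-based scoring of
    fixed-size gene subsets on 2-D UMAP embeddings, per-gene perturbation
    scores with core-gene calling, maximum mean discrepancy and SVM-based
    evaluation of synthetic data, hypergeometric over-representation tests
    with Benjamini-Yekutieli correction, and a two-phenotype synthetic-data
    generator with planted signal genes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    e1071,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse
SystemRequirements: Python (>= 3.9) with numpy and umap-learn on PATH as
    'python' (used for 2-D UMAP embeddings in the screening module)
Config/testthat/edition: 3
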