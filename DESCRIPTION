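Package: cryptphylo
Title: Somatic Phylogenomics of Clonal Epithelial Crypts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of per-crypt somatic variant read counts from
    laser-capture microdissected epithelial crypts: exact-binomial germline
    filtering and beta-binomial overdispersion (rho) artifact filtering,
    maximum-parsimony crypt phylogenies with maximum-likelihood placement of
    mutations on branches, SBS96 and ID83 mutation spectra, de novo mutational
    signature extraction by a hierarchical Dirichlet process sampler or by NMF,
    EM deconvolution against a reference catalogue with residual ("unknown")
    signature construction, and mutation burden and rate statistics including a
    mixed-model cohort comparison. Includes a synthetic cohort generator that
    emulates clonal crypt sequencing with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    lme4,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
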