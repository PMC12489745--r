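Package: popgea
Title: Population Structure, Diversity and Genotype-Environment Association from SNP Dosages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for post-variant-calling population genomics of
    non-model diploids: VCF quality filtering, linkage-disequilibrium decay and
    pruning, PCA/k-means/DAPC and admixture inference with cross-validation,
    PCA-Mahalanobis selection-outlier scanning, Nei and Weir-Cockerham
    diversity and differentiation statistics, Weir-Goudet population-specific
    beta-FST and allele-sharing beta-kinship with inbreeding, KING-robust
    relatedness pruning, and triple-evidence genotype-environment association
    combining partial redundancy analysis, latent-factor ridge models and the
    outlier scan. Includes a seedable genotype-environment simulator
    (Balding-Nichols drift, selfing, pedigree relatives, admixture,
    environmentally driven loci) so every stage is testable without
    access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
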