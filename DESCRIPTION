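Package: traitpd
Title: Trait Probability Distributions for Functional Diversity with
    Intraspecific Variation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trait-based diversity analysis for community ecology built on
    trait probability distributions (TPD). Individual-level morphological
    measurements are allometrically standardized, ordinated by PCA, and turned
    into species-level Gaussian trait probability distributions on a
    discretized trait grid, with an imputation rule for sparsely measured
    species. From community-level distributions the package computes
    functional richness, functional redundancy, Rao's quadratic entropy, and
    community weighted means, plus taxonomic and functional beta diversity
    partitioned into turnover and nestedness components (Sorensen/Simpson
    family). Inference tools cover one-way ANOVA with Tukey contrasts gated by
    a Shapiro-Wilk normality check (falling back to Kruskal-Wallis with Dunn
    tests), one-factor PERMANOVA, Mantel tests, and Moran's I, all with seeded
    permutation engines. A synthetic community generator with habitat
    filtering and known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
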