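Package: augselect
Title: Augmented-Block Trial Analysis and Rank-Sum Genotype Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for early-generation plant-breeding trials laid
    out as Federer augmented block designs: error and block effects are
    estimated from replicated check cultivars, unreplicated test genotypes are
    adjusted by block, and per-trait genetic parameters (variance components,
    broad-sense heritability, genotypic and environmental coefficients of
    variation, expected selection gain) are derived from the adjusted values.
    Genotypes are ranked per trait and combined with the Mulamba-Mock
    sum-of-ranks index, optionally weighted by the genotypic coefficients of
    variation, and truncated at a selection intensity.  Selected genotypes are
    characterized by Z-score standardization, Euclidean/UPGMA clustered
    heatmaps, principal component analysis with variable contributions, and a
    Pearson correlation network of traits.  Includes fruit-level trait
    derivation (CIELab hue angle and chroma, marketable-size filtering) and a
    synthetic augmented-trial generator with known genetic architecture for
    validation by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    MASS,
    yaml,
    jsonlite,
    igraph,
    pheatmap,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
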