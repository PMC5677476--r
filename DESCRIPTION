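Package: traitaxes
Title: Whole-Plant Economic Spectrum Analysis with Phylogenetic
    Comparative Methods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tests whether leaf, stem and fine-root economic traits of
    tree species align along a single interspecific axis. Derives seven
    tissue traits (LMA, LTD, LDMC, WD, WDMC, RTD, RDMC) from raw organ
    measurements, computes relative growth rates from repeated stem
    measurements, and analyses species means with phylogenetically
    corrected principal components analysis, an eigenvalue-variance
    phenotypic integration index, Kaiser-rule dimensionality,
    standardized major axis regressions on raw species means and on
    phylogenetically independent contrasts, random-effects meta-analysis
    of site-level trait-growth correlations, Wilcoxon signed-rank paired
    environment comparisons, and an environment-mixing resampling null
    that quantifies how divergent intraspecific trait responses can mask
    interspecific correlations. A synthetic-data module generates
    phylogenies, correlated Brownian-motion trait means, environment
    reaction norms, individual replicates and growth records so the full
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    metafor,
    stats,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
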