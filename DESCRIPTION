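Package: grainbeta
Title: Multi-Grain Beta Diversity of Ecological Communities via Hill
    Numbers and Multi-Assemblage Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how beta diversity of ecological
    communities (ground-foraging ant assemblages in oil palm and forest
    being the motivating system) depends on sampling grain. Implements
    Hill-number alpha diversity, equal-weight gamma/alpha partitioning,
    the multi-assemblage overlap family CqN (generalised Sorensen, Horn
    and Morisita-Horn indices) and its beta complement, allometric
    conversion of abundance counts to biomass, hierarchical pooling of
    plots into nested sampling grains by spatial proximity, sample-based
    rarefaction and coverage estimation, bootstrap standard errors,
    standardized Z tests and Benjamini-Hochberg false discovery rate
    control, plus a synthetic-landscape generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
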