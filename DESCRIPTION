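Package: lymphovasc
Title: Quantitative Lymphovascular and Immune Mapping for Multiplexed Chromogenic IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to segment and phenotype tumor-associated blood and
    lymphatic vessels and immune infiltrates in registered single-marker
    images from sequential chromogenic immunohistochemistry. Separates
    hematoxylin and AEC chromogens by optical-density color deconvolution,
    aligns staining rounds by translation, derives tissue and
    intratumoral/peritumoral masks from hematoxylin and S100, segments
    vascular objects and gates them into lymphovascular subtypes by
    hierarchical marker gating, segments and classes single leukocytes,
    detects tertiary lymphoid structures, and computes region-stratified
    densities, proportions and infiltration metrics with the accompanying
    statistical comparisons. Includes a seeded synthetic-image generator
    with ground truth so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
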