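Package: funcpart
Title: Variance Partitioning and Driver Attribution for Community
    Functional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Splits station-by-feature functional abundance tables (for
    example Pfam-domain counts from marine metatranscriptomes) into
    features driven by abiotic environmental gradients and features
    driven by the relative abundance of collinear taxon groups such as
    dinoflagellates and diatoms.  Implements per-feature fixed-effect
    variance-fraction decomposition, a dominant-driver attribution rule,
    dual single-taxon models with Venn reconciliation, a region
    permutation test with a Bonferroni family, quantile normalization,
    Hellinger transformation, Bray-Curtis principal coordinates
    analysis, environmental PCA, rarefaction expectations, and
    Pfam-to-KEGG-Orthology aggregation, together with a synthetic
    community generator with planted drivers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
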