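Package: anxitrends
Title: Search-Query Surveillance of Population Anxiety Themes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline for infodemiological surveillance of anxiety through
    search-engine query volumes. Identifies anxiety-related search themes from query
    logs by context-keyword co-occurrence scoring, reconstructs a common volume scale
    from window-normalized trends data by anchor stitching, builds country-by-theme
    monthly volume panels, and runs descriptive correlation analyses, k-means trend
    clustering with correlation similarity, a cross-country OLS interaction model
    classifying compensatory and noncompensatory effects, and rank-based
    country-attribute association tests. Includes a synthetic-data generator with
    planted structure (trend classes, interaction signs, geographic correlation
    blocks, a pandemic-like shock) so that every stage is testable without access to
    proprietary query logs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    sandwich,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
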