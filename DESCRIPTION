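Package: semdim
Title: Semantic Dimension Norms and Exclusivity for Abstract Concepts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for multidimensional norming studies of abstract
    concepts. Takes long-format multi-rater Likert ratings of words on
    psycholinguistic variables, affective norms and eight semantic dimensions
    (introspective, mental state, quantitative, spatial, social, moral,
    theoretical, economic); applies rater-level careless-responding exclusion
    and response-level 3-SD trimming; computes inter-rater reliability
    (Cronbach's alpha) per variable; aggregates trimmed responses into
    word-level norms; scores each abstract word's exclusivity
    E = (max - min) / sum x 100 over the eight dimension means and stratifies
    words into low/medium/high levels by percentiles; derives
    representative-dimension label sets (mean > 3.5), exact-combination
    intersection tables, and a dimension co-occurrence network with a
    reproducible two-cluster partition. Includes a synthetic rating generator
    with planted careless raters, outliers, and a semantic-diversity variable
    negatively coupled to latent exclusivity, so the whole pipeline is
    testable without access to collected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
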