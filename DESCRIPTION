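Package: toxpiscreen
Title: ToxPi Prioritization of High-Throughput Screening Data for
    Metabolic Disruptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms chemical-by-assay high-throughput screening results
    (hit calls, AC50 potencies, cytotoxicity-distance z-scores) into
    specificity-weighted input values, scores chemicals against six expert-
    curated biological-process ToxPi models for diabetes and obesity
    (adipocyte differentiation, feeding behavior in rodents and C. elegans,
    insulin sensitivity, islet cell function, beta cell function), ranks and
    percentile-bands the library, profiles chemical-chemical similarity via
    binned z-score fingerprints with pairwise-complete Pearson correlation,
    and clusters ToxPi profiles with PCA and k-means. Includes a synthetic
    data generator that emulates the structure of a sparse screening release
    with planted mechanism archetypes for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
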