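Package: comorbidnet
Title: Chronological Comorbidity Networks from Longitudinal Diagnosis Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterises the chronological accumulation of comorbidities in
    longitudinal electronic health record data. Extracts first occurrences of
    three-digit ICD-9 diagnoses, computes the pairwise chronological relative
    risk for every ordered diagnosis pair, builds the directed network of
    relative risks above one, and summarises it with edge density, reciprocity,
    breadth-first diameter, Kleinberg hub/authority scores, PageRank, and
    two-level map-equation (Infomap-style) community detection. Ego views and
    greedy maximum-relative-risk trajectories describe disease progression
    around focal diagnoses. A synthetic cohort simulator with planted
    directional hazard structure and community blocks makes every stage
    testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
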