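Package: radgraph
Title: Temporal Referral Extraction and Imaging-Record Graphs from Radiology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts temporal referrals (dates of comparison exams) from
    free-text German radiology reports and represents a longitudinal imaging
    record as a directed, queryable graph. Provides a synthetic report
    generator with gold annotations, IOB2 sentence/token processing, a
    natively implemented bidirectional LSTM named-entity tagger with a
    rule-based baseline, rule-based date normalization, confidence-graded
    linking of referrals to prior exams, graph construction and export
    (GraphML, CSV, Cypher), exploration queries including missing-comparison
    detection, and corpus-level referencing statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
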