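Package: citance
Title: Mining, Searching and Comparing Cited Statements in Full-Text Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts Cited Statements (citing sentences together with the
    identifiers of the works they cite) from JATS-formatted full-text
    articles, indexes them for keyword search with BM25 relevance and a
    shared-citation tie-break, and measures how much information a citing
    statement carries beyond the title/abstract or full text of the
    document it cites, via set differences of normalized text
    fingerprints. Includes a deterministic synthetic JATS corpus generator
    with exact ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
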