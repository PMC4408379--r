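Package: ptmenrich
Title: Post-Translational Modification Enrichment Analysis from Swiss-Prot Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Curates a database of post-translationally modified proteins from
    UniProtKB/Swiss-Prot flat-file (DAT) annotations, organises the controlled
    PTM vocabulary as a three-level rooted DAG (root, keyword terms, feature
    terms), and tests user protein lists for over-represented PTM terms with an
    exact hypergeometric tail probability and Bonferroni or Benjamini-Hochberg
    multiple-testing correction. Includes two-list integration/matching,
    per-organism PTM frequency analysis, delimited-table and bar-chart export,
    and a synthetic Swiss-Prot fixture generator with planted enrichment for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
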