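Package: estcurate
Title: Curation and Digital Expression Mining of Clone-Named EST Libraries
Version: 0.1.0
Authors@R:
    person("EST", "Curation Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating and mining expressed sequence tag (EST)
    libraries whose reads carry 96-well clone names (library stem, batch,
    plate, well, read direction). Parses clone names, collapses bidirectional
    and repeated sequencing of the same clone into unique-clone counts,
    detects plate-level bookkeeping errors (well slips, duplicated or
    triplicated plates, swapped plate pairs, partial duplications, and
    cross-library plate misassignments) with a gene-identifier dot-plot
    diagonal scan, and estimates per-gene expression as EST frequency per
    10,000 clones. Differential expression between library groups is tested
    with a multigroup chi-squared statistic and the exact Audic-Claverie test
    with Bonferroni control; downstream helpers provide average-linkage
    clustering on correlation distance, log2 ratio tables, and cross-platform
    directional concordance. A synthetic-catalog generator with an exact
    truth ledger makes every stage testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
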