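Package: dgepair
Title: Two-Library Digital Gene Expression Profiling with the
    Audic-Claverie Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Count-based differential expression analysis for a pair of
    sequencing libraries, as used for EST/tag transcriptome surveys such
    as the light-induced sporulation response of Physarum polycephalum.
    Implements the Audic-Claverie conditional count test in log space
    (robust to p-values below 1e-250), relative-frequency quantitation
    and library summaries, ranked differential-expression reporting,
    Fisher exact GO-term overrepresentation with false-discovery-rate
    control, guilt-by-association network assembly from prior
    interaction tables, and a seeded two-library count simulator with
    planted fold changes and GO enrichment for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
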