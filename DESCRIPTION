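Package: bovcdr3
Title: Bovine Immunoglobulin Heavy-Chain CDR3 Extraction and
    Ultralong-Repertoire Analysis
Version: 0.1.0
Authors@R:
    person("Repertoire", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stepwise, motif-anchored pipeline for analysing bovine B-cell
    receptor heavy-chain amplicon sequencing data.  Reads are gated by
    length and quality, oriented by mismatch-tolerant primer search,
    screened for isotype-determining motifs, deduplicated, and the CDR3
    junction (conserved cysteine 104 through tryptophan 118, IMGT
    numbering) is extracted between pre- and post-CDR3 anchor motifs.
    Downstream tools classify junction lengths (short/medium/ultralong),
    compute productivity and ultralong percentages under both total and
    productive denominators, assign V/D/J germline genes against a toy
    reference, collapse clonotypes, and compare longitudinal timepoints
    with exact paired Wilcoxon signed-rank tests.  A nanopore-like
    amplicon simulator with full ground truth exercises every branch of
    the cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
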