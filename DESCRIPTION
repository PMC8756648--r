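Package: spscreen
Title: Analytics for Genome-Wide Bacterial Signal Peptide Secretion Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of genome-wide Sec signal
    peptide screening in lactic acid bacteria: parsing of cleavage-site
    prediction output and arrow-notation peptide tables, per-peptide sequence
    properties (N-domain net charge, hydrophobicity, Ala-X-Ala signal
    peptidase I motif), group comparison of secreting versus non-secreting
    peptides, pairwise shared-signal-peptide (Jaccard) similarity matrices
    across strain panels, fluorescence plate-screen shortlisting with
    triplicate confirmation, in-silico assembly of signal-peptide::protease
    fusion constructs, and seeded synthetic-data generators with planted
    ground truth for every input class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
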