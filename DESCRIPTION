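Package: protcleave
Title: Protease Prediction from Peptide Termini with Specificity-Matrix
    Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for tracing naturally occurring peptides back to the
    proteases that may have generated them.  Reconstructs N- and
    C-terminal cleavage-site windows from peptide coordinates on a parent
    protein, matches the windows against curated protease/cleavage-site
    associations, scores unmatched termini with per-position specificity
    matrices using a log-likelihood compared to the exact score
    distribution over all possible sites, applies a percentile match rule
    with banded confidence levels and exopeptidase rescue, and
    corroborates candidate proteolysis events by organism identity and
    cellular co-location through a lightweight protein/GO/taxon knowledge
    model.  Includes a seeded synthetic-benchmark generator and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
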