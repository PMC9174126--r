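Package: corefucq
Title: Site-Specific Quantification of Core-Fucosylated Glycopeptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and tandem mass tag (TMT) quantification of
    core-fucosylated N-glycopeptides that have been simplified by Endo F3
    partial deglycosylation, which leaves only the innermost GlcNAc (plus the
    alpha1-6 core fucose, when present) attached to the peptide. Provides
    monoisotopic mass arithmetic for peptides, modifications and glycan
    remnants; FASTA ingestion, in-silico tryptic digestion and N-glycosylation
    sequon scanning; theoretical b/y fragment ladders with glycan
    retention/loss variants, precursor signature-loss ions, oxonium
    diagnostics and TMT reporter ions; a seeded synthetic-spectrum generator
    emulating a two-condition, two-replicate knockdown design; a simplified
    target-decoy search engine with q-value estimation, glycosylation-site
    localization, median-normalized reporter quantification and
    extracted-ion-chromatogram integration; and multi-criterion ranking of
    candidate fucosyltransferase substrate proteins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
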