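Package: ripscan
Title: Prediction of Regulated Intramembrane Proteolysis of Membrane-Bound
    Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: In silico prediction of proteolytic activation of membrane-bound
    transcription factors (MB-TFs) by regulated intramembrane proteolysis (RIP).
    Compiles degenerate intramembrane-protease recognition motifs (S1P, rhomboid)
    into executable patterns and scans them in transmembrane-domain (TMD) anchored
    windows; profiles structural features that facilitate RIP (helix-breaking
    motifs, positively charged residues in the TMD and its flanks); classifies
    membrane topology and the membrane side of the transcription factor family
    domain; tests feature enrichment against whole-proteome and membrane-proteome
    backgrounds with hypergeometric statistics and Bonferroni correction; builds
    bootstrap consensus trees of TMD peptides; integrates the evidence into a
    tiered per-protein candidate report; and predicts functions of TFs from
    GO-term enrichment of their target genes. A synthetic-data generator with
    recorded ground truth makes every stage testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: MAFFT
Config/testthat/edition: 3
RoxygenNote: 7.3.3
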