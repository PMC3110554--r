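Package: hpulse
Title: Hydrophobic Pulse Detection and Transmembrane Unit Segmentation for Helical Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects hydrophobic pulses in the primary sequence of alpha-helical
    integral membrane proteins. A hydrophobic pulse is a rise-then-fall of
    Kyte-Doolittle hydropathy, detected as the first position of a run of
    positive sign-consensus of a sinus-weighted hydrophobicity-variation score
    computed over five window radii (small-event group G1, n = 2..6; large-event
    group G2, n = 12..16) via a 4-of-5 sign-consensus finite-state automaton.
    G2 pulses segment a sequence into transmembrane units (TMUs) grouping a
    transmembrane helix with adjacent small helices; G1 pulses mark helix
    extremities, kinks and other local irregularities. The package includes
    readers for FASTA, STRIDE output and PDBTM XML annotations, evaluation
    utilities against per-residue structural annotations, a deterministic
    synthetic membrane-protein generator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
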