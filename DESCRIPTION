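Package: venomtk
Title: Transcriptome-to-Proteome Discovery and Structural Characterization of Venom Peptide Toxins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering disulfide-rich peptide toxins from
    venom-gland transcriptomes and confirming them in venom proteomes.
    Annotates toxin precursors (signal peptide, propeptide ending in a
    processing quadruplet motif, mature region, C-terminal amidation
    signal), performs in-silico protease digestion with modification
    enumeration and theoretical b/y fragment generation, matches tandem
    mass spectra against a target-decoy database with PSM-level FDR
    control, detects isotope clusters in MS1 data and matches intact
    proteoforms under disulfide/amidation hypotheses, and computes
    geometry-level structural metrics for inhibitor-cystine-knot (ICK)
    peptides: disulfide detection, turn classification, ICK topology,
    Kabsch superposition, the Q structure-similarity score, NOE
    calibration and disulfide restraint generation. Ships synthetic-data
    generators with machine-readable ground truth for every stage.
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
    utils,
    xml2,
    yaml
Suggests: testthat (>= 3.0.0), bio3d
Config/testthat/edition: 3
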