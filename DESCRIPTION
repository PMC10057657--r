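Package: mirtriage
Title: Tri-Omics Triage of miRNA-Attributable Protein Changes in Tumor
    and Xenograft Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls differentially expressed miRNAs across
    tumor/adjacent-normal/patient-derived-xenograft contrasts with
    empirical-Bayes moderated statistics and a fold-change, p-value and
    overall-F FDR filter cascade; builds priority miRNA lists (largest
    changes up and down, and changes in the same direction in both
    comparisons); filters predicted miRNA-target interactions by binding
    probability, 3'UTR site and validation status; attributes
    subcellular-fraction protein changes to specific miRNAs by
    inverse-direction matching and elimination of mRNA-concordant
    (transcriptionally explained) proteins; classifies xenograft protein
    identifications as human or murine from peptide evidence; and ships a
    synthetic tri-omics generator with planted ground truth so the whole
    analysis is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
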