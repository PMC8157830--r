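Package: diagprimer
Title: Design and In-Silico Evaluation of Species-Diagnostic PCR Primers from DNA Barcodes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building species-diagnostic PCR assays from aligned
    DNA-barcode panels (typically the mitochondrial CO1 barcode region).
    Finds fixed diagnostic nucleotide differences between a target species
    and a panel of confounder species, designs primer candidates whose
    3'-termini sit on those sites with strongly inhibitory mismatch types
    (G/A and C/C doublets weighted highest), estimates melting temperatures
    (Wallace rule and unified nearest-neighbor thermodynamics), screens
    primer pairs by mismatch-tolerant in-silico PCR with a Primer-BLAST
    style rejection rule, and catalogues barcode haplotypes with predicted
    amplification success per haplotype and geographic region, including a
    minimum-spanning haplotype network. Ships the published Trissolcus
    japonicus primer pair TJ234F/TJ460R as a preset, and a synthetic-panel
    simulator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
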