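Package: aggscan
Title: Saturation Mutagenesis Sort-Seq Analysis of Alpha-Synuclein Aggregation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a FRET-sorting saturation mutagenesis screen
    of alpha-synuclein amyloid seeding. Enumerates NNS single-codon variant
    libraries, counts variants in merged amplicon reads by exact matching,
    computes per-variant relative enrichment (log10 fold change versus wild
    type), estimates the screen false discovery rate from stop codons,
    classifies inhibitory residues by Otsu thresholding of per-residue median
    enrichment, and embeds mutational profiles by t-SNE. Companion stages
    post-filter cross-linking mass spectrometry identifications into replicate
    consensus contact maps scored against conformational ensembles, and compute
    NMR chemical shift perturbations between assigned HSQC peak lists. A
    seeded synthetic-data generator emulates every input with known ground
    truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    cluster,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
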