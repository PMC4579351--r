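Package: exoarch
Title: Promoter Architecture Analysis of Yeast Ribosomal Protein Genes from ChIP-exo Data
Version: 0.1.0
Authors@R:
    person("Exoarch", "Developers", email = "exoarch@example.org", role = c("aut", "cre"))
Description: A tested pipeline for dissecting the promoter architecture of
    coregulated yeast ribosomal protein genes (RPGs) at near base-pair
    resolution from strand-specific ChIP-exo exonuclease stop-site tags and
    MNase fragment data. Provides GeneTrack-style smoothed peak calling and
    opposite-strand peak pairing, IUPAC and position-weight-matrix motif
    scanning with exact p-values, factor occupancy tables with log2-median
    and percent-rank normalization, Hmo1 binding-breadth classification,
    anchor-aligned orientation-corrected composite profiles, piggyback
    pattern-similarity scoring, nucleosome dyad positioning and +1-nucleosome
    shift estimation, and a fully parameterized synthetic ChIP-exo/MNase data
    generator with retained ground truth so every stage is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
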