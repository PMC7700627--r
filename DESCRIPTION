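Package: genefamr
Title: Genome-Wide Characterization of Protein Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for genome-wide characterization of protein gene
    families such as the heat-shock protein (HSP) chaperones. Identifies
    family members by exact Smith-Waterman local alignment with
    Karlin-Altschul E-values, profiles proteins with ProtParam-style
    physicochemical calculators (molecular weight, isoelectric point,
    aliphatic index, instability index, GRAVY) and the associated
    acidic/unstable/thermostable/hydrophilic classifications, discovers
    conserved ungapped motifs by ZOOPS expectation-maximization, builds
    neighbor-joining and JTT maximum-likelihood phylogenies with bootstrap
    supports, and classifies codon-level synonymous and non-synonymous
    substitutions and indels between orthologous coding sequences,
    summarised as count-based Ka/Ks tables. Ships seeded simulators for
    divergent CDS pairs, paralog families with planted motifs, and protein
    evolution along a phylogeny, so every stage is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    phangorn,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
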