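Package: neosex
Title: Degeneration, Allelic Expression and Chromatin of Young Neo-Sex Chromosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis toolkit for the early stages of Y-chromosome degeneration
    on recently formed (neo-)sex chromosomes. Classifies variant calls into
    fixed neo-X/neo-Y differences versus segregating polymorphism, reconstructs
    the neo-Y sequence from male-specific variants, calls degenerate neo-Y
    genes (premature stop codons and frameshifts), dates the X/Y split from
    silent-site divergence, computes pairwise NG86 Ka/Ks and codon-usage bias
    statistics (Fop, CBI, CAI), tests per-gene allele-specific expression with
    DNA-based normalization and Fisher exact tests, derives active-gene and
    bound/unbound cutoffs from density crossings, and profiles chromatin marks
    with scaled metagene bound-fraction curves. A seeded simulator generates
    every pipeline input with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
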