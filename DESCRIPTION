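Package: bulkLR
Title: Ligand-Receptor Crosstalk Scoring for Bulk RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Infers putative ligand-receptor interactions between two cell
    populations profiled by bulk RNA-seq, adapted from the CellPhoneDB
    strategy for the low-replicate bulk setting. Provides counts-per-million
    and FPKM normalization, threshold-based differential-expression
    filtering, exclusive-intersection (UpSet) decomposition of gene sets
    across comparisons, a ligand-receptor interaction score with a
    gene-role permutation null, and a negative-binomial synthetic-data
    generator emulating a two-genotype, two-condition oligodendrocyte
    precursor cell design paired with naive/EAE microglia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
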