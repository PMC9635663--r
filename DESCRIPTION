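Package: phamr
Title: Assembly and Quality Control of Phage Gene Phamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles phage protein-coding genes into phamilies ("phams") by
    amino-acid sequence similarity. Genes are parsed from GenBank flat files or
    FASTA, translated with the bacterial genetic code, deduplicated, and
    clustered over a pairwise homology graph (BLOSUM62 local alignments with
    affine gaps, filtered by identity, bidirectional coverage and E-value)
    using set-cover, single-linkage or greedy-incremental cluster modes, with
    optional cascaded clustering and a profile-sequence merge stage for remote
    homologs. Includes alignment-based audits for false-positive and
    false-negative pham members, pangenome-style conservation reports
    (core/soft-core/shell/cloud, presence-absence matrix, genome-to-pham map),
    consensus functional annotations with synonym normalization, a two-stage
    parameter grid-search harness, and a deterministic synthetic-genome
    fixture generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
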