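test_that("translate_cds follows the bacterial code with initiator and stop rules", {
  expect_equal(translate_cds("ATGGCTTAA"), "MA")
  expect_equal(translate_cds("GTGGCTTAA"), "MA") # GTG initiator renders M
  expect_equal(translate_cds("TTGGCTTAA"), "MA")
  expect_equal(translate_cds("CTGGCTTAA"), "LA") # CTG is not promoted
  expect_equal(translate_cds("ATGNNNTAA"), "MX") # ambiguity renders X
  expect_error(translate_cds("ATGTAAGCT"), "internal stop")
  expect_error(translate_cds("ATGGC"), "multiple of 3")
})

test_that("synonymous substitutions leave the protein unchanged", {
  # CTT -> CTC (Leu), GCT -> GCA (Ala), AAA -> AAG (Lys)
  expect_equal(translate_cds("ATGCTTGCTAAATAA"),
               translate_cds("ATGCTCGCAAAGTAA"))
})

write_test_genbank <- function(path) {
  # 3 CDS: plain with /translation, complement(join()) translated from the
  # span, and one whose span holds an internal stop (must be skipped)
  prot <- "MKVLANDERW"
  cds2 <- "ATGAAAGTTCTTGCTAATGATGAACGTTGGTAA" # MKVLANDERW + TAA
  bad <- "ATGGCTGCTGCTTAAGCTGCTGCTTAA" # TAA at codon 5 of 9
  spacer <- paste(rep("ACGT", 25), collapse = "")
  genome <- paste0(spacer, cds2, spacer, bad, spacer)
  # complement(join()) span: place revcomp(cds2) and describe it in 2 exons
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds2)))
  genome <- paste0(genome, rc, "ACGT")
  s2 <- 101L; e2 <- s2 + nchar(cds2) - 1L
  sb <- e2 + 101L; eb <- sb + nchar(bad) - 1L
  sj <- eb + 101L; ej <- sj + nchar(rc) - 1L
  mid <- sj + 14L
  lines <- c(
    sprintf("LOCUS       TESTPHG1 %d bp    DNA     linear   PHG", nchar(genome)),
    "DEFINITION  Crafted test phage.",
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(genome)),
    "     CDS             1..30",
    "                     /locus_tag=\"GENE_A\"",
    "                     /product=\"portal",
    "                     protein\"",
    sprintf("                     /translation=\"%s\"", prot),
    sprintf("     CDS             %d..%d", s2, e2),
    "                     /locus_tag=\"GENE_B\"",
    "                     /product=\"terminase, large subunit\"",
    sprintf("     CDS             %d..%d", sb, eb),
    "                     /locus_tag=\"GENE_BAD\"",
    sprintf("     CDS             complement(join(%d..%d,%d..%d))",
            sj, mid, mid + 1L, ej),
    "                     /locus_tag=\"GENE_C\"",
    "ORIGIN",
    paste0("        1 ", tolower(genome)),
    "//"
  )
  writeLines(lines, path)
  list(prot = prot, expect_bc = "MKVLANDERW")
}

test_that("GenBank parsing captures CDS features, qualifiers and strands", {
  gb <- withr::local_tempfile(fileext = ".gbk")
  info <- write_test_genbank(gb)
  expect_warning(g <- read_genome(gb), "GENE_BAD")
  expect_equal(nrow(g), 3) # internal-stop CDS skipped
  expect_setequal(g$gene_id, c("GENE_A", "GENE_B", "GENE_C"))
  a <- g[g$gene_id == "GENE_A", ]
  expect_equal(a$protein, info$prot) # /translation wins
  expect_equal(a$annotation, "portal protein") # folded qualifier
  expect_equal(g$protein[g$gene_id == "GENE_B"], info$expect_bc)
  cc <- g[g$gene_id == "GENE_C", ]
  expect_equal(cc$protein, info$expect_bc) # complement(join()) span
  expect_equal(cc$strand, "-")
  expect_true(all(diff(g$start) > 0)) # ordered by start
})

test_that("FASTA protein input yields records without coordinates", {
  fa <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">g1 portal protein", "MKVLANDERWMKVL",
               ">g2", "MAAAAKVLANDERW"), fa)
  g <- read_genome(fa)
  expect_equal(nrow(g), 2)
  expect_true(all(is.na(g$start)))
  expect_equal(g$annotation, c("portal protein", ""))
  expect_equal(g$gene_id, c("g1", "g2"))
})

test_that("FASTA nucleotide input is translated per record", {
  fa <- withr::local_tempfile(fileext = ".fna")
  writeLines(c(">g1", "ATGAAAGTTCTTGCTAATGATGAACGTTGGTAA"), fa)
  g <- read_genome(fa)
  expect_equal(g$protein, "MKVLANDERW")
})

test_that("deduplicate collapses exact duplicates and conserves genes", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    protein = c("MKVLANDERW", "MAAAAKVLAN", "MKVLANDERW", "MCCCCKVLAN",
                "MDDDDKVLAN")
  )
  nr <- deduplicate(genes)
  expect_equal(nrow(nr), 4)
  expect_equal(sum(lengths(nr$gene_ids)), 5)
  expect_equal(anyDuplicated(nr$protein), 0L)
  # all unique
  nr2 <- deduplicate(genes[2:5, ])
  expect_equal(nrow(nr2), 4)
  # empty
  expect_equal(nrow(deduplicate(genes[0, ])), 0)
})

test_that("expand_clusters inverts deduplication and conserves genes", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:5),
    protein = c("MKVLANDERW", "MAAAAKVLAN", "MKVLANDERW", "MCCCCKVLAN",
                "MDDDDKVLAN")
  )
  nr <- deduplicate(genes)
  ident <- tibble::tibble(nr_id = nr$nr_id, cluster = seq_len(nrow(nr)))
  out <- expand_clusters(ident, nr)
  expect_setequal(out$gene_id, genes$gene_id) # round trip
  expect_equal(nrow(out), 5)
  # identical sequences land together
  expect_equal(out$cluster[out$gene_id == "g1"],
               out$cluster[out$gene_id == "g3"])
  # everything in one cluster
  one <- tibble::tibble(nr_id = nr$nr_id, cluster = 1L)
  expect_equal(nrow(expand_clusters(one, nr)), 5)
  expect_error(expand_clusters(ident[-1, ], nr), "cover")
  expect_error(
    expand_clusters(dplyr::bind_rows(ident,
                                     tibble::tibble(nr_id = "zz",
                                                    cluster = 9L)), nr),
    "absent")
})
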