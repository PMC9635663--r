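test_that("false-positive detection applies the length and score rules", {
  # identical sequences: nothing to flag
  same <- tibble::tibble(gene_id = c("a", "b", "c"),
                         protein = rep(strrep("MKVLANDERW", 10), 3))
  expect_equal(nrow(find_false_positives(same)), 0L)
  # singleton phams cannot contain false positives
  expect_equal(nrow(find_false_positives(same[1, ])), 0L)

  # 50-residue member in a pham whose longest member is 100: 50 < 60
  fam <- generate_family(100, 3, 0.9, seed = 41L, indel_prob = 0)
  short <- substr(fam[1], 1, 50)
  memb <- tibble::tibble(gene_id = c("m1", "m2", "m3", "frag"),
                         protein = c(fam, short))
  flags <- find_false_positives(memb)
  expect_equal(flags$gene_id, "frag")
  expect_equal(flags$reason, "length")
  expect_equal(flags$statistic, 0.5)

  # random interloper of full length gets the score flag
  set.seed(42)
  memb2 <- tibble::tibble(gene_id = c("m1", "m2", "m3", "bad"),
                          protein = c(fam, random_aa(100)))
  flags2 <- find_false_positives(memb2)
  expect_equal(flags2$gene_id, "bad")
  expect_equal(flags2$reason, "score")
  expect_lt(flags2$statistic, 0.5)
})

test_that("flags at a threshold persist at stricter score thresholds", {
  fam <- generate_family(100, 3, 0.9, seed = 43L, indel_prob = 0)
  set.seed(44)
  memb <- tibble::tibble(gene_id = c("m1", "m2", "m3", "bad"),
                         protein = c(fam, random_aa(100)))
  loose <- find_false_positives(memb, qc_thresholds())
  stricter <- find_false_positives(
    memb, qc_thresholds(fp_score_threshold = 0.25))
  # genes passing at 0.5 still pass at 0.25; flags can only drop
  expect_true(all(stricter$gene_id %in% loose$gene_id))
})

test_that("representative selection maximizes mean similarity with tie-breaks", {
  one <- tibble::tibble(gene_id = "solo", protein = "MKVLANDERW")
  expect_equal(select_representative(one), "solo")

  # ancestor with two divergent descendants: ancestor is closest to both
  anc <- generate_family(80, 1, 1, seed = 45L)
  kids <- purrr::map_chr(1:2, function(i) {
    set.seed(46L + i)
    ch <- strsplit(anc, "")[[1]]
    flip <- sample(seq_along(ch), 28)
    for (pos in flip) {
      ch[pos] <- sample(setdiff(rownames(blosum62())[1:20], ch[pos]), 1)
    }
    paste(ch, collapse = "")
  })
  trio <- tibble::tibble(gene_id = c("anc", "kid1", "kid2"),
                         protein = c(anc, kids))
  expect_equal(select_representative(trio), "anc")

  # two identical members and one divergent: smallest id of the pair wins
  pair <- tibble::tibble(gene_id = c("b", "a", "z"),
                         protein = c(anc, anc, kids[1]))
  expect_equal(select_representative(pair), "a")
})

test_that("false negatives: the withheld homolog is found, thresholds bind", {
  fx <- trapfree_fixture()
  cache <- shared_cache()
  members <- fx$genes |>
    dplyr::inner_join(fx$truth[, c("gene_id", "family")], by = "gene_id") |>
    dplyr::transmute(pham_id = as.integer(factor(family)),
                     gene_id = gene_id, protein = protein)
  # the truth assignment of well-separated families is FN-free
  expect_equal(nrow(find_false_negatives(members, cache = cache)), 0L)

  # withhold one member of family 1 into its own pham
  withheld <- members
  fam1 <- withheld$pham_id[withheld$gene_id == "F01M01"]
  withheld$pham_id[withheld$gene_id == "F01M02"] <- 999L
  fns <- find_false_negatives(withheld, cache = cache)
  expect_equal(fns$gene_id[fns$pham_id == fam1], "F01M02")

  # an E-value cap below any achievable hit reports nothing
  tiny <- qc_thresholds(fn_evalue = 1e-300)
  expect_equal(nrow(find_false_negatives(withheld, tiny, cache = cache)),
               0L)
})

test_that("audit aggregates both detectors with the exact fp-rate formula", {
  fx <- trap_fixture()
  cache <- shared_cache()
  members <- fx$genes |>
    dplyr::inner_join(fx$truth[, c("gene_id", "family")], by = "gene_id") |>
    dplyr::transmute(pham_id = as.integer(factor(family)),
                     gene_id = gene_id, protein = protein)
  qc <- audit_phams(members, cache = cache)
  expect_s3_class(qc, "pham_qc")
  expect_equal(qc$fp_rate, nrow(qc$false_positives) / nrow(members))
  # the planted short fragment is the one flagged member
  expect_equal(qc$false_positives$gene_id, "TRAPFRAG")
  expect_equal(qc$false_positives$reason, "length")
  tl <- tidy(qc)
  expect_true(all(c("pham_id", "gene_id", "flag_type") %in% names(tl)))
  expect_equal(glance(qc)$fp_rate, qc$fp_rate)
})
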