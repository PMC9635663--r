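test_that("global alignment statistics match hand-derived cases", {
  r <- global_align("AAAA", "AAAA")
  expect_equal(r$raw_score, 16) # 4 x BLOSUM62 A/A = 4
  expect_equal(r$identity, 1)
  expect_equal(r$gap_fraction, 0)
  expect_equal(r$normalized_score, 4)
  expect_equal(r$coverage_query, 1)
  expect_equal(r$coverage_target, 1)

  # one gap of length 2: 2*4 - (11 + 1) = -4, 2 gap columns of 4
  r2 <- global_align("AAAA", "AA")
  expect_equal(r2$raw_score, -4)
  expect_equal(r2$alignment_length, 4L)
  expect_equal(r2$gap_fraction, 0.5)

  set.seed(41)
  for (i in 1:5) {
    s <- random_aa(sample(10:40, 1))
    rs <- global_align(s, s)
    expect_equal(rs$identity, 1)
    expect_equal(rs$similarity, 1)
    expect_equal(rs$gap_fraction, 0)
    expect_true(rs$identity <= rs$similarity)
  }
})

test_that("global score is symmetric and identity never exceeds similarity", {
  set.seed(42)
  for (i in 1:20) {
    a <- random_aa(sample(5:30, 1))
    b <- random_aa(sample(5:30, 1))
    ra <- global_align(a, b)
    rb <- global_align(b, a)
    expect_equal(ra$raw_score, rb$raw_score)
    expect_true(ra$identity <= ra$similarity + 1e-12)
    expect_equal(ra$normalized_score,
                 ra$raw_score / ra$alignment_length)
  }
})

test_that("local alignment recovers a planted shared domain", {
  set.seed(7)
  domain <- random_aa(20)
  a <- paste0(random_aa(40), domain, random_aa(40))
  b <- paste0(random_aa(40), domain, random_aa(40))
  r <- local_align(a, b)
  expect_true(r$identity > 0.5) # dominated by the identical domain
  expect_lt(abs(r$coverage_query - 0.2), 0.1)
  expect_lt(abs(r$coverage_target - 0.2), 0.1)
  rs <- local_align(a, a)
  expect_equal(rs$coverage_query, 1)
  expect_equal(rs$coverage_target, 1)
})

test_that("scores agree exactly with an independent DP oracle on short pairs", {
  set.seed(11)
  for (i in 1:40) {
    a <- random_aa(sample(1:12, 1))
    b <- random_aa(sample(1:12, 1))
    expect_equal(global_align(a, b)$raw_score,
                 oracle_align_score(a, b, local = FALSE))
    expect_equal(local_align(a, b)$raw_score,
                 oracle_align_score(a, b, local = TRUE))
  }
})

test_that("scores agree with Biostrings pairwiseAlignment", {
  # second independent route; gapOpening = 10 / gapExtension = 1 is the
  # BLAST -11/-1 convention (gap of length L costs 10 + L)
  B <- blosum62()
  set.seed(12)
  for (i in 1:10) {
    a <- random_aa(sample(10:60, 1))
    b <- random_aa(sample(10:60, 1))
    pg <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = B,
                                        gapOpening = 10, gapExtension = 1,
                                        type = "global", scoreOnly = TRUE)
    expect_equal(global_align(a, b)$raw_score, pg)
    pl <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = B,
                                        gapOpening = 10, gapExtension = 1,
                                        type = "local", scoreOnly = TRUE)
    expect_equal(local_align(a, b)$raw_score, max(pl, 0))
  }
})

test_that("random unrelated pairs fall under the 0.5 half-bit global threshold", {
  set.seed(13)
  n_below <- 0L
  trials <- 200L
  for (i in seq_len(trials)) {
    r <- global_align(random_aa(50), random_aa(50))
    if (r$normalized_score < 0.5) n_below <- n_below + 1L
  }
  expect_gte(n_below / trials, 0.95)
})

test_that("E-values behave like Karlin-Altschul statistics", {
  sc <- scoring_scheme()
  expect_equal(compute_evalue(0, 100, 50, 1e4, sc),
               sc$karlin_k * 100 * 1e4)
  expect_equal(compute_evalue(30, 100, 50, 2e4, sc),
               2 * compute_evalue(30, 100, 50, 1e4, sc))
  expect_gt(compute_evalue(20, 100, 50, 1e4, sc),
            compute_evalue(40, 100, 50, 1e4, sc))
  expect_error(compute_evalue(10, 0, 50, 1e4, sc), "positive")
})

test_that("the alignment cache is symmetric, correct and counts work", {
  cache <- alignment_cache()
  a <- "MKVLANDERW"
  b <- "MKVLANDEAW"
  r1 <- local_align(a, b, cache = cache)
  r2 <- local_align(b, a, cache = cache)
  expect_equal(cache$n_aligned, 1L)
  expect_equal(r1$raw_score, r2$raw_score)
  expect_equal(r1$coverage_query, r2$coverage_target)
  fresh <- local_align(a, b)
  expect_equal(r1, fresh)

  # all-vs-all over n sequences computes exactly n(n-1)/2 alignments
  set.seed(14)
  seqs <- replicate(6, random_aa(15))
  cache2 <- alignment_cache()
  for (i in seq_along(seqs)) {
    for (j in seq_along(seqs)) {
      if (i != j) local_align(seqs[i], seqs[j], cache = cache2)
    }
  }
  expect_equal(cache2$n_aligned, 15L)
})

test_that("empty sequences are rejected", {
  expect_error(global_align("", "MKV"), "non-empty")
  expect_error(local_align("MKV", ""), "non-empty")
})
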