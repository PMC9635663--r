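path_graph <- function(lens = c(10, 10, 10, 10)) {
  homology_graph(
    tibble::tibble(nr_id = c("A", "B", "C", "D"), length = lens),
    tibble::tibble(from = c("A", "B", "C"), to = c("B", "C", "D"))
  )
}

test_that("cluster modes interpret small graphs as specified", {
  g <- path_graph()
  # single linkage: one component
  m1 <- cluster_graph(g, 1)
  expect_equal(length(unique(m1$cluster)), 1L)
  # set cover on the path: B and C both cover 3; B wins the id tie-break
  m0 <- cluster_graph(g, 0)
  cl <- split(m0$nr_id, m0$cluster)
  expect_equal(length(cl), 2L)
  expect_setequal(cl[[1]], c("A", "B", "C"))
  expect_setequal(cl[[2]], "D")
  # triangle plus isolate: {A,B,C}, {D} under every mode
  tri <- homology_graph(
    tibble::tibble(nr_id = c("A", "B", "C", "D"), length = rep(10, 4)),
    tibble::tibble(from = c("A", "A", "B"), to = c("B", "C", "C"))
  )
  for (mode in 0:2) {
    p <- cluster_graph(tri, mode)
    byc <- split(p$nr_id, p$cluster)
    expect_setequal(purrr::map_chr(byc, paste, collapse = ""),
                    c("ABC", "D"))
  }
  expect_error(cluster_graph(g, 5), "unknown cluster mode")
})

test_that("set cover refines components and greedy-incremental follows length order", {
  # longer D should seed its own cluster first in mode 2
  g <- path_graph(lens = c(10, 10, 10, 30))
  m2 <- cluster_graph(g, 2)
  expect_equal(m2$cluster[m2$nr_id == "D"], m2$cluster[m2$nr_id == "C"])
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:30, 1)
    ids <- sprintf("n%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    edges <- tibble::tibble(
      from = sample(ids, ne, replace = TRUE),
      to = sample(ids, ne, replace = TRUE)
    ) |> dplyr::filter(from != to)
    g <- homology_graph(tibble::tibble(nr_id = ids,
                                       length = sample(50:500, n)), edges)
    n0 <- length(unique(cluster_graph(g, 0)$cluster))
    n1 <- length(unique(cluster_graph(g, 1)$cluster))
    expect_gte(n0, n1)
    # every mode yields an exact partition
    for (mode in 0:2) {
      p <- cluster_graph(g, mode)
      expect_setequal(p$nr_id, ids)
      expect_equal(anyDuplicated(p$nr_id), 0L)
    }
  }
})

test_that("identical sequences always share an edge; unrelated ones never do", {
  nr <- tibble::tibble(nr_id = c("a", "b"),
                       protein = rep(strrep("MKVLANDERW", 3), 2))
  g <- build_graph(nr, cluster_params(min_seq_id = 0.5, coverage = 0.9,
                                      evalue = 1e-10))
  expect_equal(nrow(g$edges), 1L)
  set.seed(32)
  rand <- tibble::tibble(nr_id = sprintf("r%02d", 1:15),
                         protein = replicate(15, random_aa(100)))
  g2 <- build_graph(rand, cluster_params()) # 0.3 / 0.7 / 1e-3
  expect_equal(nrow(g2$edges), 0L)
})

test_that("coverage thresholds exclude domain-chain pairs", {
  set.seed(33)
  domain <- random_aa(60)
  p1 <- paste0(random_aa(100), domain, random_aa(100))
  p2 <- paste0(random_aa(100), domain, random_aa(100))
  st <- local_align(p1, p2)
  expect_lt(max(st$coverage_query, st$coverage_target), 0.7)
  nr <- tibble::tibble(nr_id = c("a", "b"), protein = c(p1, p2))
  g <- build_graph(nr, cluster_params(coverage = 0.7))
  expect_equal(nrow(g$edges), 0L)
})

test_that("edge detection is monotone in thresholds and sensitivity", {
  fx <- trapfree_fixture()
  nr <- deduplicate(fx$genes[1:24, ]) # families 1-3
  cache <- shared_cache()
  g_strict <- build_graph(nr, cluster_params(min_seq_id = 0.5,
                                             coverage = 0.8),
                          cache = cache)
  g_loose <- build_graph(nr, cluster_params(min_seq_id = 0.3,
                                            coverage = 0.7),
                         cache = cache)
  expect_lte(nrow(g_strict$edges), nrow(g_loose$edges))
  key <- function(g) paste(g$edges$from, g$edges$to)
  expect_true(all(key(g_strict) %in% key(g_loose)))
  # pham count under mode 1 is non-increasing as thresholds relax
  expect_gte(length(unique(cluster_graph(g_strict, 1)$cluster)),
             length(unique(cluster_graph(g_loose, 1)$cluster)))
  # lower sensitivity can only remove candidate pairs
  g_s4 <- build_graph(nr, cluster_params(min_seq_id = 0.3, coverage = 0.7,
                                         sensitivity = 4), cache = cache)
  expect_true(all(key(g_s4) %in% key(g_loose)))
})

test_that("cascaded clustering degenerates and agrees on easy fixtures", {
  fx <- generate_fixture(fixture_spec(n_families = 3,
                                      members_per_family = 4,
                                      identities = c(0.9, 0.6, 0.4),
                                      n_orphams = 0,
                                      ancestor_length = 100, seed = 9L))
  nr <- deduplicate(fx$genes)
  cache <- alignment_cache()
  params1 <- cluster_params(min_seq_id = 0.35, cluster_steps = 1)
  params2 <- cluster_params(min_seq_id = 0.35, cluster_steps = 2)
  a <- cascade_cluster(nr, params1, cache = cache)
  b <- cascade_cluster(nr, params2, cache = cache)
  expect_equal(adjusted_rand_index(a$cluster, b$cluster), 1)
  one <- deduplicate(fx$genes[1, ])
  for (steps in c(1L, 3L)) {
    p <- cascade_cluster(one, cluster_params(cluster_steps = steps))
    expect_equal(nrow(p), 1L)
    expect_equal(p$cluster, 1L)
  }
})

test_that("profile merging joins remote sub-families and only coarsens", {
  sf <- remote_subfamily_genes()
  cache <- shared_cache()
  nr <- deduplicate(sf)
  p1 <- cascade_cluster(nr, cluster_params(), cache = cache)
  expect_gte(length(unique(p1$cluster)), 2L)
  merged <- profile_merge(p1, nr, cluster_params(min_seq_id = 0.15,
                                                 coverage = 0.6),
                          cache = cache)
  expect_equal(length(unique(merged$cluster)), 1L)
  # no cross-pham hits leaves the partition untouched
  fx <- trapfree_fixture()
  orph <- deduplicate(fx$genes[grepl("ORPH", fx$genes$gene_id), ])
  po <- cascade_cluster(orph, cluster_params(), cache = cache)
  mo <- profile_merge(po, orph, cluster_params(min_seq_id = 0.15,
                                               coverage = 0.6),
                      cache = cache)
  expect_equal(mo, po)
  # coarsening: members of one input cluster never split
  joined <- dplyr::inner_join(p1, merged, by = "nr_id",
                              suffix = c("_in", "_out"))
  split_check <- joined |>
    dplyr::group_by(cluster_in) |>
    dplyr::summarise(n_out = dplyr::n_distinct(cluster_out))
  expect_true(all(split_check$n_out == 1))
})

test_that("more profile iterations find at least the same merges", {
  sf <- remote_subfamily_genes()
  cache <- shared_cache()
  nr <- deduplicate(sf)
  p1 <- cascade_cluster(nr, cluster_params(), cache = cache)
  m1 <- profile_merge(p1, nr, cluster_params(min_seq_id = 0.15,
                                             coverage = 0.6,
                                             num_iterations = 1),
                      cache = cache)
  m2 <- profile_merge(p1, nr, cluster_params(min_seq_id = 0.15,
                                             coverage = 0.6,
                                             num_iterations = 2),
                      cache = cache)
  # m2 is a coarsening of m1 (supersets of merges)
  joined <- dplyr::inner_join(m1, m2, by = "nr_id",
                              suffix = c("_1", "_2"))
  split_check <- joined |>
    dplyr::group_by(cluster_1) |>
    dplyr::summarise(n2 = dplyr::n_distinct(cluster_2))
  expect_true(all(split_check$n2 == 1))
})

test_that("assemble_phams handles degenerate inputs and stays a partition", {
  set.seed(34)
  genes <- tibble::tibble(
    gene_id = sprintf("u%02d", 1:6),
    genome_id = "G1",
    protein = replicate(6, random_aa(80)),
    annotation = ""
  )
  ps <- assemble_phams(genes, skip_profile = TRUE)
  expect_equal(nrow(ps$phams), 6L) # all orphams
  expect_setequal(ps$members$gene_id, genes$gene_id)
  # duplicate genome: pham count unchanged, memberships double
  twice <- dplyr::bind_rows(
    genes, dplyr::mutate(genes, gene_id = paste0(gene_id, "b"),
                         genome_id = "G2"))
  ps2 <- assemble_phams(twice, skip_profile = TRUE)
  expect_equal(nrow(ps2$phams), 6L)
  expect_true(all(ps2$phams$n_genes == 2L))
  expect_error(assemble_phams(genes[0, ]), "non-empty")
})

test_that("pham ids are ordered by size and representatives are members", {
  ps <- trapfree_assembly()
  expect_true(all(diff(ps$phams$n_genes) <= 0))
  expect_true(all(purrr::map_lgl(seq_len(nrow(ps$phams)), function(i) {
    rep_id <- ps$phams$representative[i]
    rep_id %in% ps$members$gene_id[ps$members$pham_id ==
                                     ps$phams$pham_id[i]]
  })))
  expect_setequal(ps$members$gene_id, trapfree_fixture()$genes$gene_id)
  expect_equal(anyDuplicated(ps$members$gene_id), 0L)
})

test_that("mode-1 clustering matches an independent BFS component oracle", {
  set.seed(35)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    ids <- sprintf("v%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    edges <- tibble::tibble(
      from = sample(ids, ne, replace = TRUE),
      to = sample(ids, ne, replace = TRUE)
    ) |> dplyr::filter(from != to)
    g <- homology_graph(tibble::tibble(nr_id = ids, length = 10L), edges)
    ours <- cluster_graph(g, 1)
    oracle <- bfs_components(ids, edges)
    expect_equal(adjusted_rand_index(ours$cluster, oracle[ids]), 1)
  }
})
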