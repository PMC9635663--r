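# Independent oracles and shared fixtures for the test suite.

# Plain-R Gotoh dynamic programming, scores only. Kept deliberately separate
# from the package's C++ implementation so the two can disagree.
oracle_align_score <- function(a, b, local = FALSE, open = 11, ext = 1) {
  B <- phamr::blosum62()
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca)
  m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0
    M[1, ] <- 0
  } else {
    if (n > 0) X[2:(n + 1), 1] <- -(open + (seq_len(n) - 1) * ext)
    if (m > 0) Y[1, 2:(m + 1)] <- -(open + (seq_len(m) - 1) * ext)
  }
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, Y[i, j - 1] - ext,
                     X[i, j - 1] - open)
      M[i, j] <- B[ca[i - 1], cb[j - 1]] +
        max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      if (local) {
        M[i, j] <- max(M[i, j], 0)
        best <- max(best, M[i, j])
      }
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# breadth-first-search connected components, independent of igraph
bfs_components <- function(ids, edges) {
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(edges))) {
    f <- edges$from[k]
    t <- edges$to[k]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  comp <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  cl <- 0L
  for (id in ids) {
    if (!is.na(comp[id])) next
    cl <- cl + 1L
    queue <- id
    comp[id] <- cl
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- adj[[v]][is.na(comp[adj[[v]]])]
      comp[nb] <- cl
      queue <- c(queue, nb)
    }
  }
  comp
}

adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  d <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * d / choose(n, 2)
  maxi <- (b + d) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

random_aa <- function(len) {
  paste(sample(rownames(phamr::blosum62())[1:20], len, replace = TRUE),
        collapse = "")
}

# Memoized expensive fixtures, shared across test files (built once per run).
.shared <- new.env(parent = emptyenv())

shared_cache <- function() {
  if (is.null(.shared$cache)) .shared$cache <- alignment_cache()
  .shared$cache
}

trapfree_fixture <- function() {
  if (is.null(.shared$fx)) .shared$fx <- generate_fixture(fixture_spec())
  .shared$fx
}

trapfree_assembly <- function() {
  if (is.null(.shared$ps)) {
    .shared$ps <- assemble_phams(trapfree_fixture()$genes,
                                 cache = shared_cache())
  }
  .shared$ps
}

trap_fixture <- function() {
  if (is.null(.shared$fx_traps)) {
    .shared$fx_traps <- generate_fixture(fixture_spec(
      traps = c("domain_chain", "intein", "short_fragment")))
  }
  .shared$fx_traps
}

trap_assembly <- function() {
  if (is.null(.shared$ps_traps)) {
    .shared$ps_traps <- assemble_phams(trap_fixture()$genes,
                                       cache = shared_cache())
  }
  .shared$ps_traps
}

remote_subfamily_genes <- function() {
  if (is.null(.shared$sf)) {
    sf <- generate_remote_subfamilies(seed = 7L)
    sf$genome_id <- "G1"
    sf$annotation <- ""
    .shared$sf <- sf
  }
  .shared$sf
}
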