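#' Pairwise protein alignment with BLOSUM62 and affine gaps
#'
#' `global_align()` computes the optimal Needleman-Wunsch global alignment,
#' `local_align()` the optimal Smith-Waterman local alignment, both under the
#' scheme's substitution matrix and affine gap penalties.
#'
#' The four headline statistics share one denominator, the total number of
#' alignment columns (gap columns included): `identity` is the fraction of
#' columns pairing identical residues, `similarity` the fraction of columns
#' whose substitution score is positive, `gap_fraction` the fraction of gap
#' columns, and `normalized_score` the raw half-bit score per column.
#' Coverages are the aligned span of each sequence divided by its length; a
#' global alignment has coverage 1 on both sides by construction.
#'
#' @param a,b Protein sequences (single uppercase strings; `X` allowed).
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()]; when supplied, the unordered
#'   pair is aligned at most once.
#' @param db_size Total residue count of the search database, used for the
#'   E-value. Defaults to `nchar(b)` (a single-target database).
#' @return A one-row tibble with columns `raw_score`, `alignment_length`,
#'   `identity`, `similarity`, `gap_fraction`, `normalized_score`,
#'   `coverage_query`, `coverage_target`, `evalue`.
#' @examples
#' global_align("AAAA", "AAAA")
#' local_align("MKVLA", "MKVLA")
#' @export
global_align <- function(a, b, scheme = scoring_scheme(), cache = NULL,
                         db_size = nchar(b)) {
  align_pair(a, b, scheme, local = FALSE, cache = cache, db_size = db_size)
}

#' @rdname global_align
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), cache = NULL,
                        db_size = nchar(b)) {
  align_pair(a, b, scheme, local = TRUE, cache = cache, db_size = db_size)
}

align_pair <- function(a, b, scheme, local, cache = NULL,
                       db_size = nchar(b)) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 ||
      length(b) != 1 || is.na(a) || is.na(b) || nchar(a) == 0 ||
      nchar(b) == 0) {
    abort("alignment requires two non-empty protein strings")
  }
  if (!is.null(cache)) {
    key <- cache_key(a, b, local)
    hit <- cache$store[[key]]
    if (!is.null(hit)) {
      res <- hit
      if (hit$.swapped[[1]] != (a > b)) res <- swap_coverages(res)
      res$.swapped <- NULL
      res$evalue <- compute_evalue(res$raw_score, nchar(a), nchar(b),
                                   db_size, scheme)
      return(res)
    }
  }
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  S <- scheme$matrix[ca, cb, drop = FALSE]
  al <- align_core(S, -scheme$gap_open, -scheme$gap_extend, local)
  res <- alignment_stats(al, ca, cb, S)
  res$evalue <- compute_evalue(res$raw_score, nchar(a), nchar(b),
                               db_size, scheme)
  if (!is.null(cache)) {
    stored <- res
    stored$.swapped <- a > b
    cache$store[[key]] <- stored
    cache$n_aligned <- cache$n_aligned + 1L
  }
  res
}

seq_chars <- function(x) {
  ch <- strsplit(str_to_upper(x), "", fixed = TRUE)[[1]]
  # collapse rare ambiguity codes onto X so every residue scores
  ch[!ch %in% rownames(blosum62())] <- "X"
  ch
}

alignment_stats <- function(al, ca, cb, S) {
  ai <- al$a_idx
  bi <- al$b_idx
  len <- length(ai)
  if (len == 0) {
    return(tibble(
      raw_score = al$score, alignment_length = 0L, identity = 0,
      similarity = 0, gap_fraction = 0, normalized_score = 0,
      coverage_query = 0, coverage_target = 0, evalue = NA_real_
    ))
  }
  paired <- ai > 0 & bi > 0
  ident <- sum(paired & ca[pmax(ai, 1)] == cb[pmax(bi, 1)])
  simil <- sum(S[cbind(ai[paired], bi[paired])] > 0)
  gaps <- sum(!paired)
  span_a <- if (any(ai > 0)) diff(range(ai[ai > 0])) + 1L else 0L
  span_b <- if (any(bi > 0)) diff(range(bi[bi > 0])) + 1L else 0L
  tibble(
    raw_score = al$score,
    alignment_length = len,
    identity = ident / len,
    similarity = simil / len,
    gap_fraction = gaps / len,
    normalized_score = al$score / len,
    coverage_query = span_a / length(ca),
    coverage_target = span_b / length(cb),
    evalue = NA_real_
  )
}

swap_coverages <- function(res) {
  tmp <- res$coverage_query
  res$coverage_query <- res$coverage_target
  res$coverage_target <- tmp
  res
}

#' Karlin-Altschul expectation value
#'
#' `E = K * len_a * db_size * exp(-lambda * S)` with the scheme's gapped
#' BLOSUM62(11,1) parameters applied directly to the raw half-bit score.
#'
#' @param raw_score Raw alignment score in half-bit units.
#' @param len_a,len_b Unaligned lengths of the two sequences (residues).
#' @param db_size Total residue count of the database searched.
#' @param scheme A [scoring_scheme()].
#' @return The expected number of chance alignments at least this good.
#' @examples
#' compute_evalue(50, 100, 100, 1e5)
#' @export
compute_evalue <- function(raw_score, len_a, len_b, db_size,
                           scheme = scoring_scheme()) {
  if (any(len_a <= 0) || any(len_b <= 0) || any(db_size <= 0)) {
    abort("sequence and database lengths must be positive")
  }
  scheme$karlin_k * len_a * db_size * exp(-scheme$karlin_lambda * raw_score)
}

#' Alignment result cache
#'
#' A mutable cache keyed by the unordered pair of sequences (so it is
#' symmetric in argument order and deduplication-aware: identical sequences
#' share cache entries regardless of gene identity). Pass it to
#' [global_align()]/[local_align()] or graph-building functions to avoid
#' recomputing alignments; `n_aligned` counts dynamic-programming runs
#' actually performed.
#'
#' @return An environment of class `alignment_cache` with fields `store`
#'   (environment of results) and `n_aligned` (integer counter).
#' @examples
#' cache <- alignment_cache()
#' global_align("MKV", "MKL", cache = cache)
#' global_align("MKL", "MKV", cache = cache) # served from cache
#' cache$n_aligned
#' @export
alignment_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$store <- new.env(parent = emptyenv())
  e$n_aligned <- 0L
  class(e) <- "alignment_cache"
  e
}

#' @export
print.alignment_cache <- function(x, ...) {
  cat("<alignment_cache>", length(ls(x$store)), "entries,",
      x$n_aligned, "alignments computed\n")
  invisible(x)
}

cache_key <- function(a, b, local) {
  pair <- if (a <= b) c(a, b) else c(b, a)
  paste0(if (local) "L|" else "G|", pair[1], "|", pair[2])
}
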