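#' Center-star multiple sequence alignment
#'
#' Aligns every member globally to a chosen center sequence and merges the
#' pairwise alignments under the "once a gap, always a gap" rule. This is
#' deterministic and dependency-free; it is the alignment used for profile
#' construction and the optional per-pham aligned FASTA output.
#'
#' @param seqs Character vector of protein sequences (named or not).
#' @param center Index of the center sequence (default: the first).
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return Character vector of aligned sequences (equal widths), same order
#'   and names as `seqs`.
#' @export
center_star_msa <- function(seqs, center = 1L, scheme = scoring_scheme(),
                            cache = NULL) {
  if (length(seqs) == 0) abort("cannot align an empty set of sequences")
  if (length(seqs) == 1) return(seqs)
  cseq <- seqs[[center]]
  cch <- seq_chars(cseq)
  L <- length(cch)

  members <- purrr::map(seq_along(seqs), function(i) {
    sch <- seq_chars(seqs[[i]])
    if (i == center) {
      return(list(aligned = cch, ins = vector("list", L + 1L)))
    }
    S <- scheme$matrix[cch, sch, drop = FALSE]
    al <- align_core(S, -scheme$gap_open, -scheme$gap_extend, FALSE)
    aligned <- rep("-", L)
    ins <- vector("list", L + 1L)
    pos <- 0L
    for (k in seq_along(al$a_idx)) {
      ci <- al$a_idx[k]
      si <- al$b_idx[k]
      if (ci > 0) {
        pos <- ci
        aligned[pos] <- if (si > 0) sch[si] else "-"
      } else {
        ins[[pos + 1L]] <- c(ins[[pos + 1L]], sch[si])
      }
    }
    list(aligned = aligned, ins = ins)
  })

  master_ins <- purrr::map_int(seq_len(L + 1L), function(slot) {
    max(purrr::map_int(members, ~ length(.x$ins[[slot]])))
  })

  out <- purrr::map_chr(members, function(mb) {
    parts <- character(0)
    for (slot in 0:L) {
      insres <- mb$ins[[slot + 1L]]
      pad <- master_ins[slot + 1L] - length(insres)
      parts <- c(parts, insres, rep("-", pad),
                 if (slot < L) mb$aligned[slot + 1L])
    }
    paste(parts, collapse = "")
  })
  names(out) <- names(seqs)
  out
}

#' Build a position-specific scoring profile from an aligned pham
#'
#' Columns score residue `a` as `2 * log2((f_ia + beta * p_a) /
#' ((1 + beta) * p_a))` half-bits, with observed column frequencies `f_ia`
#' (gaps excluded), pseudocount weight `beta = 1`, and BLOSUM62 background
#' frequencies `p_a`. A single-member pham yields a profile equivalent to
#' the sequence's BLOSUM62 substitution-score rows, so profile-sequence
#' search degenerates gracefully to sequence-sequence search.
#'
#' @param msa Character vector of column-aligned member sequences (equal
#'   widths; a single unaligned sequence is also accepted).
#' @param scheme A [scoring_scheme()].
#' @return An object of class `pham_profile`: list with `scores` (columns x
#'   20 residue matrix, half-bits), `consensus` (string), `length`,
#'   `n_members`.
#' @export
build_profile <- function(msa, scheme = scoring_scheme()) {
  if (length(msa) == 0) abort("profile requires at least one sequence")
  widths <- nchar(msa)
  if (length(unique(widths)) != 1) {
    abort("ragged alignment: member sequences differ in width")
  }
  bg <- blosum62_background()
  if (length(msa) == 1) {
    ch <- seq_chars(msa[[1]])
    ch <- ch[ch != "-"]
    scores <- scheme$matrix[ch, AA_STANDARD, drop = FALSE]
    dimnames(scores) <- list(NULL, AA_STANDARD)
    return(structure(
      list(scores = scores, consensus = paste(ch, collapse = ""),
           length = length(ch), n_members = 1L),
      class = "pham_profile"
    ))
  }
  mat <- do.call(rbind, strsplit(str_to_upper(msa), "", fixed = TRUE))
  ncols <- ncol(mat)
  scores <- matrix(0, nrow = ncols, ncol = 20,
                   dimnames = list(NULL, AA_STANDARD))
  consensus <- character(ncols)
  beta <- 1
  for (j in seq_len(ncols)) {
    counts <- table(factor(mat[, j], levels = AA_STANDARD))
    tot <- sum(counts)
    if (tot == 0) {
      consensus[j] <- "X" # column of gaps/ambiguity only: neutral
      next
    }
    f <- as.numeric(counts) / tot
    scores[j, ] <- 2 * log2((f + beta * bg) / ((1 + beta) * bg))
    consensus[j] <- AA_STANDARD[which.max(counts)]
  }
  structure(
    list(scores = scores, consensus = paste(consensus, collapse = ""),
         length = ncols, n_members = length(msa)),
    class = "pham_profile"
  )
}

#' @export
print.pham_profile <- function(x, ...) {
  cat("<pham_profile>", x$length, "columns from", x$n_members, "member(s)\n")
  invisible(x)
}

#' Align a profile against a protein sequence
#'
#' Smith-Waterman local alignment of a position-specific scoring profile
#' (query) against a sequence (target), under the scheme's affine gap
#' penalties. Identity is computed against the profile's consensus sequence;
#' `coverage_query` is the fraction of profile columns spanned.
#'
#' @param profile A [build_profile()] result.
#' @param seq Protein sequence string.
#' @param scheme A [scoring_scheme()].
#' @param db_size Database size in residues for the E-value (default
#'   `nchar(seq)`).
#' @return A one-row tibble with the same columns as [local_align()].
#' @export
profile_align <- function(profile, seq, scheme = scoring_scheme(),
                          db_size = nchar(seq)) {
  if (nchar(seq) == 0) abort("cannot align a profile to an empty sequence")
  cb <- seq_chars(seq)
  idx <- match(cb, AA_STANDARD)
  S <- matrix(0, nrow = profile$length, ncol = length(cb))
  ok <- !is.na(idx)
  S[, ok] <- profile$scores[, idx[ok], drop = FALSE]
  al <- align_core(S, -scheme$gap_open, -scheme$gap_extend, TRUE)
  ca <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  res <- alignment_stats(al, ca, cb, S)
  res$evalue <- compute_evalue(res$raw_score, profile$length, nchar(seq),
                               db_size, scheme)
  res
}
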