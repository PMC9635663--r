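#' Quality-control thresholds for pham auditing
#'
#' Defaults follow the published audit procedure: a member is a likely
#' false positive when its length is under 60% of the longest pham member
#' or its best within-pham global alignment scores under 0.5 half-bits per
#' column; a likely false negative is a gene outside the pham whose local
#' alignment to the pham representative has E-value at most 0.001, query
#' coverage at least 60%, and query length no less than 60% of the subject
#' length.
#'
#' @param fp_length_fraction Minimum member length as a fraction of the
#'   longest pham member.
#' @param fp_score_threshold Minimum best within-pham normalized score
#'   (half-bits per alignment column).
#' @param fn_evalue Maximum E-value for the false-negative search.
#' @param fn_query_coverage Minimum aligned fraction of the representative.
#' @param fn_length_fraction Minimum query length as a fraction of subject
#'   length.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(fp_length_fraction = 0.60,
                          fp_score_threshold = 0.5,
                          fn_evalue = 0.001,
                          fn_query_coverage = 0.60,
                          fn_length_fraction = 0.60) {
  fracs <- c(fp_length_fraction, fn_query_coverage, fn_length_fraction)
  if (any(fracs <= 0 | fracs > 1)) abort("fractions must lie in (0, 1]")
  structure(
    list(fp_length_fraction = fp_length_fraction,
         fp_score_threshold = fp_score_threshold,
         fn_evalue = fn_evalue,
         fn_query_coverage = fn_query_coverage,
         fn_length_fraction = fn_length_fraction),
    class = "qc_thresholds"
  )
}

#' Flag likely false-positive members of one pham
#'
#' Within-pham all-vs-all global alignments. A member is flagged with
#' reason `"length"` when its protein is shorter than
#' `fp_length_fraction` times the longest member, and with reason
#' `"score"` when its best within-pham length-normalized score falls below
#' `fp_score_threshold` half-bits per column. Singleton phams cannot
#' contain false positives.
#'
#' @param members Tibble with columns `gene_id` and `protein` (one pham).
#' @param thresholds A [qc_thresholds()].
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return Tibble with columns `gene_id`, `reason`, `statistic`,
#'   `threshold`; zero rows when nothing is flagged.
#' @export
find_false_positives <- function(members, thresholds = qc_thresholds(),
                                 scheme = scoring_scheme(), cache = NULL) {
  empty <- tibble(gene_id = character(), reason = character(),
                  statistic = numeric(), threshold = numeric())
  if (nrow(members) < 2) return(empty)
  lens <- nchar(members$protein)
  longest <- max(lens)
  useqs <- unique(members$protein)
  k <- length(useqs)
  norm <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      counts_i <- sum(members$protein == useqs[i])
      if (i == j && counts_i < 2) next # no identical partner to align to
      st <- global_align(useqs[i], useqs[j], scheme, cache = cache)
      norm[i, j] <- norm[j, i] <- st$normalized_score
    }
  }
  seq_of <- match(members$protein, useqs)
  best <- vapply(seq_of, function(kk) {
    max(norm[kk, ], na.rm = TRUE)
  }, numeric(1))
  out <- list()
  for (g in seq_len(nrow(members))) {
    ratio <- lens[g] / longest
    if (ratio < thresholds$fp_length_fraction) {
      out[[length(out) + 1L]] <- tibble(
        gene_id = members$gene_id[g], reason = "length",
        statistic = ratio, threshold = thresholds$fp_length_fraction
      )
    } else if (best[g] < thresholds$fp_score_threshold) {
      out[[length(out) + 1L]] <- tibble(
        gene_id = members$gene_id[g], reason = "score",
        statistic = best[g], threshold = thresholds$fp_score_threshold
      )
    }
  }
  if (length(out) == 0) empty else list_rbind(out)
}

#' Select a pham representative
#'
#' The member with the highest average similarity (fraction of
#' positive-scoring alignment columns) to all other members; a singleton
#' pham represents itself. Ties break by longest sequence, then smallest
#' gene id.
#'
#' @inheritParams find_false_positives
#' @return The representative's `gene_id`.
#' @export
select_representative <- function(members, scheme = scoring_scheme(),
                                  cache = NULL) {
  if (nrow(members) == 0) abort("cannot pick a representative of nothing")
  pham_representative_id(members$gene_id, members$protein, scheme, cache)
}

#' Find likely false-negative pham members
#'
#' Searches each pham representative against every nonredundant sequence in
#' the dataset with a local alignment; hits passing the E-value, query
#' coverage and relative-length thresholds whose gene does not belong to
#' the pham are reported as false negatives of that pham.
#'
#' @param members Tibble with columns `pham_id`, `gene_id`, `protein`
#'   covering the whole clustered dataset (a partition).
#' @param thresholds A [qc_thresholds()].
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return Tibble with columns `pham_id`, `gene_id`.
#' @export
find_false_negatives <- function(members, thresholds = qc_thresholds(),
                                 scheme = scoring_scheme(), cache = NULL) {
  nr <- deduplicate(members)
  db_size <- sum(nchar(nr$protein))
  gene_pham <- setNames(members$pham_id, members$gene_id)
  out <- list()
  for (pid in sort(unique(members$pham_id))) {
    sub <- members[members$pham_id == pid, ]
    rep_id <- select_representative(sub, scheme, cache)
    rep_seq <- sub$protein[sub$gene_id == rep_id][1]
    for (k in seq_len(nrow(nr))) {
      subj <- nr$protein[k]
      if (all(gene_pham[nr$gene_ids[[k]]] == pid)) next
      if (nchar(rep_seq) < thresholds$fn_length_fraction * nchar(subj)) next
      st <- local_align(rep_seq, subj, scheme, cache = cache,
                        db_size = db_size)
      if (st$evalue > thresholds$fn_evalue) next
      if (st$coverage_query < thresholds$fn_query_coverage) next
      hits <- nr$gene_ids[[k]]
      hits <- hits[gene_pham[hits] != pid]
      if (length(hits)) {
        out[[length(out) + 1L]] <- tibble(pham_id = pid, gene_id = hits)
      }
    }
  }
  if (length(out) == 0) {
    tibble(pham_id = integer(), gene_id = character())
  } else {
    list_rbind(out)
  }
}

#' Audit a pham assignment for false positives and negatives
#'
#' Runs both detectors over a full pham assignment and aggregates them into
#' a report. The false-positive rate is the number of flagged genes divided
#' by the number of genes being clustered.
#'
#' @param x A `pham_set` from [assemble_phams()], or a tibble with columns
#'   `pham_id`, `gene_id`, `protein`.
#' @param thresholds A [qc_thresholds()].
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return An object of class `pham_qc`: list with `false_positives`
#'   (tibble: `pham_id`, `gene_id`, `reason`, `statistic`, `threshold`),
#'   `false_negatives` (tibble: `pham_id`, `gene_id`), `fp_rate`,
#'   `fn_count`, `n_genes`.
#' @export
audit_phams <- function(x, thresholds = qc_thresholds(),
                        scheme = scoring_scheme(), cache = NULL) {
  members <- if (inherits(x, "pham_set")) x$members else as_tibble(x)
  req <- c("pham_id", "gene_id", "protein")
  if (!all(req %in% names(members))) {
    abort("audit needs columns pham_id, gene_id, protein")
  }
  if (is.null(cache)) cache <- alignment_cache()
  fps <- members |>
    group_by(.data$pham_id) |>
    group_map(function(sub, key) {
      flags <- find_false_positives(sub, thresholds, scheme, cache)
      if (nrow(flags)) flags$pham_id <- key$pham_id[[1]]
      flags
    }) |>
    list_rbind()
  if (nrow(fps)) {
    fps <- select(fps, "pham_id", "gene_id", "reason", "statistic",
                  "threshold")
  } else {
    fps <- tibble(pham_id = integer(), gene_id = character(),
                  reason = character(), statistic = numeric(),
                  threshold = numeric())
  }
  fns <- find_false_negatives(members, thresholds, scheme, cache)
  structure(
    list(false_positives = fps, false_negatives = fns,
         fp_rate = nrow(fps) / nrow(members),
         fn_count = nrow(fns), n_genes = nrow(members)),
    class = "pham_qc"
  )
}

#' @export
print.pham_qc <- function(x, ...) {
  cat("<pham_qc> ", nrow(x$false_positives), " false positives (rate ",
      signif(x$fp_rate, 3), "), ", x$fn_count, " false negatives over ",
      x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Write a QC report as TSV
#'
#' One row per flag with columns `pham_id`, `gene_id`, `flag_type`,
#' `statistic`, `threshold` (`flag_type` is `fp_length`, `fp_score` or
#' `false_negative`; statistics are empty for false negatives).
#'
#' @param qc A [audit_phams()] report.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_qc_tsv <- function(qc, path) {
  tab <- tidy(qc)
  readr::write_tsv(tab, path)
  invisible(path)
}
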