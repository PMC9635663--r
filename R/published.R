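#' Printed top-20 pham tables from the reference datasets
#'
#' The published consensus-function tables for the 20 largest phams of the
#' 1,885-genome Actinobacteriophage training dataset (`"training"`) and the
#' 4,380-genome RefSeq dataset (`"refseq"`), shipped as plain TSV. Useful
#' as inputs for summary arithmetic without re-running the original
#' large-scale clusterings.
#'
#' @param dataset `"training"` or `"refseq"`.
#' @return A tibble with columns `rank`, `n_genes`, `consensus_function`,
#'   `consensus_proportion`.
#' @examples
#' sum(published_top20("training")$n_genes)
#' @export
published_top20 <- function(dataset = c("training", "refseq")) {
  dataset <- match.arg(dataset)
  f <- switch(dataset,
    training = "table3_training_top20.tsv",
    refseq = "table4_refseq_top20.tsv"
  )
  readr::read_tsv(system.file("extdata", f, package = "phamr"),
                  col_types = "iicd", progress = FALSE)
}

#' Printed whole-dataset clustering counts
#'
#' Headline counts of the two reference clusterings: total genes, phams and
#' orphams, as printed. Pham sizes beyond the top 20 were not published, so
#' mean pham size and orpham percentage are recovered from these totals via
#' [summarize_phams()] on a size vector consistent with them (see
#' [counts_to_sizes()]).
#'
#' @param dataset `"training"` or `"refseq"`.
#' @return A one-row tibble with columns `n_genes`, `n_phams`, `n_orphams`,
#'   `largest`.
#' @export
published_counts <- function(dataset = c("training", "refseq")) {
  dataset <- match.arg(dataset)
  switch(dataset,
    training = tibble(n_genes = 181625, n_phams = 17248,
                      n_orphams = 7644, largest = 946),
    refseq = tibble(n_genes = 465399, n_phams = 90644,
                    n_orphams = 50804, largest = 775)
  )
}

#' Reconstruct a pham size vector from summary counts
#'
#' Builds a deterministic vector of pham sizes with the given total gene
#' count, pham count and orpham count (mean size and orpham fraction only
#' depend on these totals, so any consistent size vector reproduces the
#' printed summary statistics exactly).
#'
#' @param n_genes,n_phams,n_orphams Totals.
#' @return An integer vector of `n_phams` sizes summing to `n_genes` with
#'   exactly `n_orphams` ones.
#' @export
counts_to_sizes <- function(n_genes, n_phams, n_orphams) {
  stopifnot(n_orphams < n_phams, n_genes >= n_phams)
  big <- n_phams - n_orphams
  rest <- n_genes - n_orphams
  base <- rest %/% big
  extra <- rest %% big
  sizes <- c(rep(1L, n_orphams), rep(base + 1L, extra),
             rep(base, big - extra))
  stopifnot(sum(sizes) == n_genes, length(sizes) == n_phams)
  sizes
}
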