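#' Write one FASTA file per pham
#'
#' Each pham is written to `pham_<id>.faa` in `dir`, headers carrying the
#' gene id and annotation; with `align = TRUE` a center-star alignment
#' around the pham representative is additionally written to
#' `pham_<id>.afa`.
#'
#' @param phams A `pham_set`.
#' @param dir Output directory (created if needed).
#' @param align Also write aligned FASTA per pham.
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return Invisibly, the written paths.
#' @export
write_pham_fastas <- function(phams, dir, align = FALSE,
                              scheme = scoring_scheme(), cache = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (pid in phams$phams$pham_id) {
    sub <- phams$members |> filter(.data$pham_id == pid)
    p <- file.path(dir, sprintf("pham_%d.faa", pid))
    writeLines(fasta_lines(sub$gene_id, sub$protein, sub$annotation), p)
    paths <- c(paths, p)
    if (align && nrow(sub) >= 1) {
      rep_id <- phams$phams$representative[phams$phams$pham_id == pid]
      center <- which(sub$gene_id == rep_id)[1]
      msa <- center_star_msa(setNames(sub$protein, sub$gene_id),
                             center = center, scheme = scheme,
                             cache = cache)
      pa <- file.path(dir, sprintf("pham_%d.afa", pid))
      writeLines(fasta_lines(sub$gene_id, unname(msa), sub$annotation), pa)
      paths <- c(paths, pa)
    }
  }
  invisible(paths)
}

fasta_lines <- function(ids, seqs, ann = NULL) {
  headers <- paste0(">", ids,
                    ifelse(!is.null(ann) & nzchar(ann %||% ""),
                           paste0(" ", ann), ""))
  as.vector(rbind(headers, seqs))
}
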