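#' Pangenome conservation category of a pham
#'
#' Classifies a pham by the percentage of genomes encoding at least one of
#' its genes: core (>99%), soft-core (>95%), shell (>15%) or cloud (>0%).
#' The thresholds are strict, so a value exactly on a boundary falls in the
#' lower category (95% is shell, 15% is cloud).
#'
#' @param percent_genomes Percentage in (0, 100]; vectorized.
#' @return A factor with levels `core`, `soft-core`, `shell`, `cloud`.
#' @examples
#' classify_conservation(c(100, 96, 50, 15))
#' @export
classify_conservation <- function(percent_genomes) {
  if (any(is.na(percent_genomes)) || any(percent_genomes <= 0) ||
      any(percent_genomes > 100)) {
    abort("percent_genomes must lie in (0, 100]")
  }
  lv <- c("core", "soft-core", "shell", "cloud")
  factor(
    ifelse(percent_genomes > 99, "core",
    ifelse(percent_genomes > 95, "soft-core",
    ifelse(percent_genomes > 15, "shell", "cloud"))),
    levels = lv
  )
}

#' Roary-style pham presence-absence summary
#'
#' For each pham: its consensus function, the number of genomes (isolates)
#' carrying it, the number of member genes, the average genes per carrying
#' genome, its conservation category, and one column per genome holding the
#' semicolon-joined gene ids present there (empty where absent).
#'
#' @param phams A `pham_set` from [assemble_phams()].
#' @param genome_ids Optional character vector of all genome ids (defaults
#'   to the genomes observed in the pham set; supply explicitly if some
#'   input genomes contributed no genes).
#' @param synonyms A synonym map for [consensus_function()] (default:
#'   the bundled starter rules).
#' @return A tibble of class `pangenome_summary`, one row per pham.
#' @export
presence_absence <- function(phams, genome_ids = NULL,
                             synonyms = default_synonym_map()) {
  members <- phams$members
  if (is.null(genome_ids)) genome_ids <- sort(unique(members$genome_id))
  if (!all(members$genome_id %in% genome_ids)) {
    abort("gene assigned to a genome absent from genome_ids")
  }
  n_genomes <- length(genome_ids)
  per <- members |>
    group_by(.data$pham_id) |>
    summarise(
      consensus_function = consensus_function(.data$annotation,
                                              synonyms)$label,
      n_isolates = n_distinct(.data$genome_id),
      n_sequences = n(),
      .groups = "drop"
    ) |>
    mutate(
      avg_seqs_per_isolate = round(.data$n_sequences / .data$n_isolates, 2),
      percent_genomes = 100 * .data$n_isolates / n_genomes,
      category = classify_conservation(.data$percent_genomes)
    )
  cells <- members |>
    group_by(.data$pham_id, .data$genome_id) |>
    summarise(genes = paste(sort(.data$gene_id), collapse = ";"),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "genome_id", values_from = "genes",
                       values_fill = "")
  for (g in setdiff(genome_ids, names(cells))) cells[[g]] <- ""
  out <- per |>
    inner_join(cells[, c("pham_id", genome_ids)], by = "pham_id") |>
    arrange(.data$pham_id)
  class(out) <- c("pangenome_summary", class(out))
  out
}

#' Map each genome to the phams its genes were assorted into
#'
#' One row per genome with the sorted, deduplicated pham ids of its genes.
#'
#' @param phams A `pham_set`.
#' @param genome_ids Optional complete set of genome ids; genomes without
#'   genes get an empty pham list.
#' @return A tibble with columns `genome_id` and `pham_ids` (list-column of
#'   sorted integer vectors).
#' @export
genome_pham_map <- function(phams, genome_ids = NULL) {
  members <- phams$members
  if (is.null(genome_ids)) genome_ids <- sort(unique(members$genome_id))
  found <- members |>
    group_by(.data$genome_id) |>
    summarise(pham_ids = list(sort(unique(.data$pham_id))),
              .groups = "drop")
  tibble(genome_id = genome_ids) |>
    left_join(found, by = "genome_id") |>
    mutate(pham_ids = purrr::map(.data$pham_ids, ~ .x %||% integer(0)))
}

#' Summary statistics of a pham set
#'
#' Pham count, total genes, mean genes per pham (2 decimals), largest pham
#' size, and orpham (single-gene pham) count and percentage (1 decimal).
#'
#' @param x A `pham_set`, or a numeric vector of pham sizes.
#' @return A one-row tibble with columns `n_phams`, `n_genes`, `mean_size`,
#'   `largest`, `n_orphams`, `pct_orphams`.
#' @examples
#' summarize_phams(c(3, 2, 1, 1))
#' @export
summarize_phams <- function(x) {
  sizes <- if (inherits(x, "pham_set")) x$phams$n_genes else as.numeric(x)
  if (length(sizes) == 0) abort("no phams to summarize")
  if (any(sizes < 1)) abort("pham sizes must be positive")
  tibble(
    n_phams = length(sizes),
    n_genes = sum(sizes),
    mean_size = round(sum(sizes) / length(sizes), 2),
    largest = max(sizes),
    n_orphams = sum(sizes == 1),
    pct_orphams = round(100 * sum(sizes == 1) / length(sizes), 1)
  )
}

#' Write the pangenome report files
#'
#' Emits `gene_presence_absence.csv` (Roary-style, quoted cells),
#' `genome_pham_map.tsv` (genome id followed by tab-separated pham ids) and
#' `summary.txt` into `dir`.
#'
#' @param phams A `pham_set`.
#' @param dir Output directory (created if needed).
#' @param genome_ids Optional complete genome id set.
#' @param synonyms Synonym map for consensus functions.
#' @return Invisibly, the paths written.
#' @export
write_pangenome <- function(phams, dir, genome_ids = NULL,
                            synonyms = default_synonym_map()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- presence_absence(phams, genome_ids, synonyms)
  pa_path <- file.path(dir, "gene_presence_absence.csv")
  utils::write.csv(as.data.frame(pa), pa_path, row.names = FALSE)
  gm <- genome_pham_map(phams, genome_ids)
  gm_path <- file.path(dir, "genome_pham_map.tsv")
  lines <- purrr::map2_chr(gm$genome_id, gm$pham_ids, function(g, p) {
    paste(c(g, p), collapse = "\t")
  })
  writeLines(lines, gm_path)
  sm <- summarize_phams(phams)
  sm_path <- file.path(dir, "summary.txt")
  writeLines(c(
    paste0("phams: ", sm$n_phams),
    paste0("genes: ", sm$n_genes),
    paste0("mean genes per pham: ", format(sm$mean_size, nsmall = 2)),
    paste0("largest pham: ", sm$largest),
    paste0("orphams: ", sm$n_orphams, " (", format(sm$pct_orphams,
                                                   nsmall = 1), "%)")
  ), sm_path)
  invisible(c(pa_path, gm_path, sm_path))
}
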