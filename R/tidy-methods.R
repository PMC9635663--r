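#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a pham set into a per-pham tibble
#'
#' @param x A `pham_set`.
#' @param ... Unused.
#' @return One row per pham: `pham_id`, `n_genes`, `n_genomes`,
#'   `representative`.
#' @export
tidy.pham_set <- function(x, ...) {
  genomes <- x$members |>
    group_by(.data$pham_id) |>
    summarise(n_genomes = n_distinct(.data$genome_id), .groups = "drop")
  x$phams |>
    inner_join(genomes, by = "pham_id") |>
    select("pham_id", "n_genes", "n_genomes", "representative")
}

#' One-row summary of a pham set
#'
#' @param x A `pham_set`.
#' @param ... Unused.
#' @return A one-row tibble: the [summarize_phams()] columns plus
#'   `n_genomes`.
#' @export
glance.pham_set <- function(x, ...) {
  summarize_phams(x) |>
    mutate(n_genomes = n_distinct(x$members$genome_id))
}

#' Tidy a QC report into one row per flag
#'
#' @param x A `pham_qc` report.
#' @param ... Unused.
#' @return Tibble with columns `pham_id`, `gene_id`, `flag_type`
#'   (`fp_length`, `fp_score`, `false_negative`), `statistic`, `threshold`.
#' @export
tidy.pham_qc <- function(x, ...) {
  fp <- x$false_positives |>
    mutate(flag_type = paste0("fp_", .data$reason)) |>
    select("pham_id", "gene_id", "flag_type", "statistic", "threshold")
  fn <- x$false_negatives |>
    mutate(flag_type = "false_negative", statistic = NA_real_,
           threshold = NA_real_)
  bind_rows(fp, fn)
}

#' One-row summary of a QC report
#'
#' @param x A `pham_qc` report.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `n_false_positives`, `fp_rate`,
#'   `fn_count`.
#' @export
glance.pham_qc <- function(x, ...) {
  tibble(n_genes = x$n_genes,
         n_false_positives = nrow(x$false_positives),
         fp_rate = x$fp_rate,
         fn_count = x$fn_count)
}

#' Pham size distribution plot
#'
#' Histogram of pham sizes on a log-scaled x axis, the standard first look
#' at a clustering (most phams are small, a few are very large).
#'
#' @param object A `pham_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pham_set <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$n_genes)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            color = "grey20") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "genes per pham", y = "phams",
                  title = "Pham size distribution") +
    ggplot2::theme_minimal()
}

#' Conservation category bar plot
#'
#' @param pa A [presence_absence()] summary.
#' @return A ggplot object.
#' @export
plot_conservation <- function(pa) {
  ggplot2::ggplot(pa, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_bar(fill = "darkorange") +
    ggplot2::labs(x = "conservation category", y = "phams") +
    ggplot2::theme_minimal()
}
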