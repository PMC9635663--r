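#' Synonym maps for functional annotations
#'
#' Phage gene annotations are free text and the same function is labeled
#' inconsistently across genomes ("terminase, large subunit", "TerL",
#' "large terminase"). A synonym map is an ordered list of case-insensitive
#' rules, each an anchored regular expression paired with a canonical
#' label, applied after whitespace/punctuation normalization; the first
#' matching rule wins. The bundled starter set covers common structural
#' gene synonyms and is meant to be extended by the user; full curation is
#' data, not code.
#'
#' @param path Two-column TSV (`pattern`, `canonical`), no header required
#'   to be quoted.
#' @return A tibble of class `synonym_map` with columns `pattern`,
#'   `canonical`.
#' @export
read_synonym_map <- function(path) {
  rules <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(rules)[1:2] <- c("pattern", "canonical")
  class(rules) <- c("synonym_map", class(rules))
  rules
}

#' @rdname read_synonym_map
#' @export
default_synonym_map <- function() {
  if (is.null(.phamr$synonyms)) {
    .phamr$synonyms <- read_synonym_map(
      system.file("extdata", "synonyms.tsv", package = "phamr")
    )
  }
  .phamr$synonyms
}

#' Normalize a functional annotation label
#'
#' Lowercases, trims and collapses whitespace, strips trailing punctuation,
#' maps empty or placeholder labels ("", "unknown", "hypothetical") to
#' `"hypothetical protein"`, then applies the first matching synonym rule.
#' Normalization is idempotent: applying it twice equals applying it once.
#'
#' @param raw Character vector of raw labels.
#' @param map A synonym map (default: the bundled starter set).
#' @return Character vector of canonical labels.
#' @examples
#' normalize_label(c("TerL", "", "Hypothetical Protein "))
#' @export
normalize_label <- function(raw, map = default_synonym_map()) {
  x <- str_squish(tolower(ifelse(is.na(raw), "", raw)))
  x <- sub("[[:punct:][:space:]]+$", "", x)
  placeholder <- x %in% c("", "hypothetical", "hypothetical protein",
                          "unknown", "unknown function", "uncharacterized",
                          "uncharacterized protein", "putative protein",
                          "conserved hypothetical protein")
  x[placeholder] <- "hypothetical protein"
  for (k in seq_len(nrow(map))) {
    hit <- grepl(paste0("^(?:", map$pattern[k], ")$"), x, perl = TRUE,
                 ignore.case = TRUE)
    x[hit] <- map$canonical[k]
  }
  x
}

#' Consensus function of a pham
#'
#' The modal normalized annotation among the members and its share of the
#' membership. Ties prefer any label over `"hypothetical protein"`, then
#' break lexicographically.
#'
#' @param labels Character vector of member annotations (or a `pham_set`
#'   member subset's `annotation` column).
#' @param map A synonym map.
#' @return A one-row tibble with columns `label`, `n`, `proportion`
#'   (percent of members, 1 decimal).
#' @examples
#' consensus_function(c("portal", "Portal", "hypothetical protein"))
#' @export
consensus_function <- function(labels, map = default_synonym_map()) {
  if (length(labels) == 0) abort("cannot take a consensus of no labels")
  norm <- normalize_label(labels, map)
  counts <- sort(table(norm), decreasing = TRUE)
  top <- counts[counts == max(counts)]
  cand <- names(top)
  real <- cand[cand != "hypothetical protein"]
  winner <- if (length(real)) sort(real)[1] else "hypothetical protein"
  tibble(
    label = winner,
    n = as.integer(counts[[winner]]),
    proportion = round(100 * counts[[winner]] / length(labels), 1)
  )
}

#' Per-pham consensus function report
#'
#' @param phams A `pham_set`.
#' @param map A synonym map.
#' @return A tibble with columns `pham_id`, `n_genes`,
#'   `consensus_function`, `consensus_proportion`.
#' @export
consensus_report <- function(phams, map = default_synonym_map()) {
  phams$members |>
    group_by(.data$pham_id) |>
    summarise(
      n_genes = n(),
      cf = list(consensus_function(.data$annotation, map)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("cf") |>
    select("pham_id", "n_genes", consensus_function = "label",
           consensus_proportion = "proportion")
}

#' Write the consensus-function report as CSV
#'
#' @param phams A `pham_set`.
#' @param path Output CSV path.
#' @param map A synonym map.
#' @return The path, invisibly.
#' @export
write_consensus_csv <- function(phams, path, map = default_synonym_map()) {
  utils::write.csv(as.data.frame(consensus_report(phams, map)), path,
                   row.names = FALSE)
  invisible(path)
}
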