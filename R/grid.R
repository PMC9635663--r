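#' Parameter grids for the two-stage training workflow
#'
#' `grid_spec()` describes a full-factorial sweep over the six clustering
#' parameters. The defaults reproduce the published grids: the
#' sequence-sequence stage enumerates 3 cluster modes x 3 cascade steps x 3
#' sensitivities x 5 identities x 5 coverages x 3 E-values = 2,025 sets,
#' and the profile-sequence stage 3 x 3 x 3 x 5 x 7 x 2 = 1,890 sets.
#'
#' @param stage `"sequence"` or `"profile"`.
#' @param cluster_mode,steps,sensitivity,min_seq_id,coverage,evalue Value
#'   lists; defaults depend on the stage.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(stage = c("sequence", "profile"),
                      cluster_mode = NULL, steps = NULL,
                      sensitivity = NULL, min_seq_id = NULL,
                      coverage = NULL, evalue = NULL) {
  stage <- match.arg(stage)
  defaults <- if (stage == "sequence") {
    list(cluster_mode = c(0, 1, 2), steps = c(1, 2, 3),
         sensitivity = c(1, 4, 7),
         min_seq_id = c(0.5, 0.45, 0.4, 0.35, 0.3),
         coverage = c(0.9, 0.85, 0.8, 0.75, 0.7),
         evalue = c(1e-10, 1e-5, 1e-3))
  } else {
    list(cluster_mode = c(0, 1, 2), steps = c(1, 2, 3),
         sensitivity = c(1, 4, 7),
         min_seq_id = c(0.35, 0.3, 0.25, 0.2, 0.15),
         coverage = c(0.85, 0.8, 0.75, 0.7, 0.65, 0.6, 0.55),
         evalue = c(1e-5, 1e-3))
  }
  vals <- list(cluster_mode = cluster_mode %||% defaults$cluster_mode,
               steps = steps %||% defaults$steps,
               sensitivity = sensitivity %||% defaults$sensitivity,
               min_seq_id = min_seq_id %||% defaults$min_seq_id,
               coverage = coverage %||% defaults$coverage,
               evalue = evalue %||% defaults$evalue)
  if (any(lengths(vals) == 0)) abort("empty value list in grid spec")
  structure(c(list(stage = stage), vals), class = "grid_spec")
}

#' Enumerate every parameter combination of a grid
#'
#' Full Cartesian product in deterministic (table) order.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per parameter set, columns
#'   `cluster_mode`, `steps`, `sensitivity`, `min_seq_id`, `coverage`,
#'   `evalue`.
#' @examples
#' nrow(enumerate_grid(grid_spec("sequence"))) # 2025
#' nrow(enumerate_grid(grid_spec("profile"))) # 1890
#' @export
enumerate_grid <- function(spec) {
  tidyr::expand_grid(
    cluster_mode = spec$cluster_mode,
    steps = spec$steps,
    sensitivity = spec$sensitivity,
    min_seq_id = spec$min_seq_id,
    coverage = spec$coverage,
    evalue = spec$evalue
  )
}

row_to_params <- function(row, stage) {
  cluster_params(
    min_seq_id = row$min_seq_id, coverage = row$coverage,
    evalue = row$evalue, sensitivity = row$sensitivity,
    cluster_mode = row$cluster_mode,
    cluster_steps = if (stage == "sequence") row$steps else 1L,
    num_iterations = if (stage == "profile") row$steps else 1L
  )
}

grid_audit <- function(genes, partition, nr, thresholds, scheme, cache) {
  members <- expand_clusters(partition, nr) |>
    rename(pham_id = "cluster") |>
    inner_join(genes[, c("gene_id", "protein")], by = "gene_id")
  qc <- audit_phams(members, thresholds, scheme, cache)
  tibble(
    n_phams = length(unique(partition$cluster)),
    n_false_positives = nrow(qc$false_positives),
    n_false_negatives = qc$fn_count,
    fp_rate = qc$fp_rate
  )
}

#' Stage-1 grid search: sequence-sequence clustering
#'
#' Clusters and audits the dataset under every parameter set of the grid.
#' Sets producing at least one pham with a false positive are excluded;
#' among the retained sets, the one with the fewest false negatives is
#' selected as the default (ties broken by fewer phams, then by grid
#' order).
#'
#' @param genes Gene table (columns `gene_id`, `protein`).
#' @param spec A sequence-stage [grid_spec()].
#' @param thresholds [qc_thresholds()] used for the audits.
#' @param scheme A [scoring_scheme()].
#' @param cache An [alignment_cache()] (shared across the whole sweep;
#'   alignments are threshold-independent, so reuse is near-total).
#' @return A list of class `grid_search` with `results` (one row per set,
#'   audit counts and runtime), `retained`, `best_params` (a
#'   [cluster_params()] or `NULL` when nothing is retained), and
#'   `best_partition`.
#' @export
run_stage1 <- function(genes, spec = grid_spec("sequence"),
                       thresholds = qc_thresholds(),
                       scheme = scoring_scheme(),
                       cache = alignment_cache()) {
  stopifnot(spec$stage == "sequence")
  nr <- deduplicate(genes)
  grid <- enumerate_grid(spec)
  rows <- vector("list", nrow(grid))
  parts <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    t0 <- proc.time()[["elapsed"]]
    part <- cascade_cluster(nr, row_to_params(row, "sequence"), scheme,
                            cache)
    audit <- grid_audit(genes, part, nr, thresholds, scheme, cache)
    audit$runtime_seconds <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- bind_cols(row, audit)
    parts[[i]] <- part
  }
  results <- list_rbind(rows) |> mutate(set_id = row_number())
  finish_search(results, parts, results$n_false_positives == 0, "sequence")
}

#' Stage-2 grid search: profile-sequence merging
#'
#' Starting from a fixed stage-1 partition, runs the profile-sequence
#' merge under every parameter set, audits the merged phams, retains sets
#' with an overall false-positive rate below `fp_cap` (0.5% by default),
#' and selects the retained set with the fewest false negatives.
#'
#' @inheritParams run_stage1
#' @param stage1_partition Tibble (`nr_id`, `cluster`) from the selected
#'   stage-1 parameters.
#' @param fp_cap Maximum tolerated false-positive rate.
#' @return A `grid_search` list, as for [run_stage1()].
#' @export
run_stage2 <- function(genes, stage1_partition,
                       spec = grid_spec("profile"), fp_cap = 0.005,
                       thresholds = qc_thresholds(),
                       scheme = scoring_scheme(),
                       cache = alignment_cache()) {
  stopifnot(spec$stage == "profile")
  nr <- deduplicate(genes)
  grid <- enumerate_grid(spec)
  rows <- vector("list", nrow(grid))
  parts <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    t0 <- proc.time()[["elapsed"]]
    part <- profile_merge(stage1_partition, nr,
                          row_to_params(row, "profile"), scheme, cache)
    audit <- grid_audit(genes, part, nr, thresholds, scheme, cache)
    audit$runtime_seconds <- proc.time()[["elapsed"]] - t0
    rows[[i]] <- bind_cols(row, audit)
    parts[[i]] <- part
  }
  results <- list_rbind(rows) |> mutate(set_id = row_number())
  finish_search(results, parts, results$fp_rate < fp_cap, "profile")
}

finish_search <- function(results, parts, keep, stage) {
  retained <- results[keep, ]
  if (nrow(retained) == 0) {
    warn("no parameter sets retained; no best set chosen")
    return(structure(list(results = results, retained = retained,
                          best_params = NULL, best_partition = NULL),
                     class = "grid_search"))
  }
  best_row <- retained |>
    arrange(.data$n_false_negatives, .data$n_phams, .data$set_id) |>
    slice(1)
  structure(
    list(results = results, retained = retained,
         best_params = row_to_params(best_row, stage),
         best_partition = parts[[best_row$set_id]]),
    class = "grid_search"
  )
}

#' @export
print.grid_search <- function(x, ...) {
  cat("<grid_search> ", nrow(x$results), " parameter sets, ",
      nrow(x$retained), " retained\n", sep = "")
  invisible(x)
}
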