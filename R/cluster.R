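#' Clustering parameters
#'
#' The six tunable parameters governing how homologous pairs are detected
#' and how the homology graph is interpreted into phams, mirroring the
#' MMseqs2-style knobs: minimum sequence identity, bidirectional coverage,
#' E-value, sensitivity, cluster mode and cascade steps (sequence stage) or
#' iterations (profile stage).
#'
#' @param min_seq_id Minimum fraction identity for an edge, in (0, 1].
#' @param coverage Minimum coverage required of *both* sequences, in (0, 1].
#' @param evalue Maximum E-value for an edge.
#' @param sensitivity One of 1, 4, 7. At 7 the all-vs-all search is
#'   exhaustive; lower values enable a shared exact 5-mer prefilter that can
#'   only remove candidate pairs, never add them.
#' @param cluster_mode 0 = greedy set cover, 1 = single linkage (connected
#'   components), 2 = greedy incremental by descending sequence length.
#' @param cluster_steps Cascaded clustering steps for the sequence stage.
#' @param num_iterations Profile-update iterations for the profile stage.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(min_seq_id = 0.30, coverage = 0.70,
                           evalue = 1e-3, sensitivity = 7,
                           cluster_mode = 0, cluster_steps = 1,
                           num_iterations = 1) {
  if (min_seq_id <= 0 || min_seq_id > 1 || coverage <= 0 || coverage > 1) {
    abort("min_seq_id and coverage must lie in (0, 1]")
  }
  if (evalue <= 0) abort("evalue threshold must be positive")
  if (!sensitivity %in% c(1, 4, 7)) abort("sensitivity must be 1, 4 or 7")
  if (!cluster_mode %in% 0:2) abort("cluster_mode must be 0, 1 or 2")
  if (cluster_steps < 1 || num_iterations < 1) {
    abort("cluster_steps and num_iterations must be >= 1")
  }
  structure(
    list(min_seq_id = min_seq_id, coverage = coverage, evalue = evalue,
         sensitivity = sensitivity, cluster_mode = as.integer(cluster_mode),
         cluster_steps = as.integer(cluster_steps),
         num_iterations = as.integer(num_iterations)),
    class = "cluster_params"
  )
}

#' Construct a homology graph object
#'
#' Mostly used internally by [build_graph()], but exported so that cluster
#' modes can be exercised on arbitrary graphs.
#'
#' @param nodes Tibble with columns `nr_id` and optionally `length`.
#' @param edges Tibble with columns `from`, `to` (nr_ids) plus any
#'   annotation columns.
#' @return An object of class `homology_graph`.
#' @export
homology_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  if (!"length" %in% names(nodes)) nodes$length <- 0L
  edges <- as_tibble(edges)
  bad <- setdiff(c(edges$from, edges$to), nodes$nr_id)
  if (length(bad)) abort("edge endpoint not among graph nodes")
  structure(list(nodes = nodes, edges = edges), class = "homology_graph")
}

#' @export
print.homology_graph <- function(x, ...) {
  cat("<homology_graph>", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the pairwise homology graph over a nonredundant sequence set
#'
#' All-vs-all Smith-Waterman local alignments, filtered by the three edge
#' thresholds: fraction identity, bidirectional coverage (both sequences
#' must be covered to at least `coverage`), and Karlin-Altschul E-value
#' against a database of all residues in the set. With `sensitivity < 7` a
#' shared exact 5-mer prefilter skips pairs with no common word.
#'
#' @param nr A nonredundant set from [deduplicate()], or any tibble with
#'   columns `nr_id` and `protein`.
#' @param params A [cluster_params()].
#' @param scheme A [scoring_scheme()].
#' @param cache Optional [alignment_cache()].
#' @return A `homology_graph` whose edges carry the alignment statistics.
#' @export
build_graph <- function(nr, params = cluster_params(),
                        scheme = scoring_scheme(), cache = NULL) {
  if (nrow(nr) == 0) abort("cannot build a graph over an empty set")
  ids <- nr$nr_id
  seqs <- setNames(nr$protein, ids)
  lens <- setNames(nchar(nr$protein), ids)
  db_size <- sum(lens)
  nodes <- tibble(nr_id = ids, length = unname(lens))
  n <- length(ids)
  if (n == 1) {
    return(homology_graph(nodes, tibble(from = character(),
                                        to = character())))
  }
  pairs <- candidate_pairs(seqs, params$sensitivity)
  if (nrow(pairs) == 0) {
    return(homology_graph(nodes, tibble(from = character(),
                                        to = character())))
  }
  res <- purrr::pmap(pairs, function(from, to) {
    st <- local_align(seqs[[from]], seqs[[to]], scheme, cache = cache,
                      db_size = db_size)
    st$from <- from
    st$to <- to
    st
  }) |> list_rbind()
  edges <- res |>
    filter(.data$identity >= params$min_seq_id,
           pmin(.data$coverage_query, .data$coverage_target) >=
             params$coverage,
           .data$evalue <= params$evalue) |>
    select("from", "to", "raw_score", "identity", "similarity",
           "gap_fraction", "normalized_score", "coverage_query",
           "coverage_target", "evalue")
  homology_graph(nodes, edges)
}

# unordered candidate pairs, optionally restricted to shared exact k-mers
candidate_pairs <- function(seqs, sensitivity, k = 5L) {
  ids <- names(seqs)
  n <- length(ids)
  all_pairs <- function() {
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    tibble(from = ids[idx[, 1]], to = ids[idx[, 2]])
  }
  if (sensitivity >= 7) return(all_pairs())
  km <- purrr::imap(seqs, function(s, id) {
    if (nchar(s) < k) return(tibble(kmer = character(), id = character()))
    tibble(kmer = unique(substring(s, 1:(nchar(s) - k + 1),
                                   k:nchar(s))), id = id)
  }) |> list_rbind()
  hits <- inner_join(km, km, by = "kmer", relationship = "many-to-many") |>
    filter(.data$id.x < .data$id.y) |>
    distinct(.data$id.x, .data$id.y)
  # preserve the deterministic i<j order of the exhaustive enumeration
  all_pairs() |>
    semi_join(hits, by = c("from" = "id.x", "to" = "id.y"))
}

#' Interpret a homology graph into clusters
#'
#' Three cluster modes: mode 1 takes connected components (single linkage);
#' mode 0 greedily picks the node covering the most still-uncovered nodes
#' (itself plus uncovered neighbors) and forms a cluster of them, repeating
#' until all nodes are covered (set cover); mode 2 walks nodes by
#' descending sequence length, each unassigned node becoming a
#' representative that absorbs its unassigned neighbors (greedy
#' incremental). Ties in mode 0 break by uncovered-neighbor count, then
#' sequence length, then lexicographically smallest id; mode 2 length ties
#' break lexicographically.
#'
#' @param g A `homology_graph`.
#' @param mode Cluster mode (0, 1 or 2).
#' @return A tibble with columns `nr_id` and integer `cluster`, a partition
#'   of the graph's nodes. Cluster ids are dense, numbered by order of
#'   first appearance in the node table.
#' @export
cluster_graph <- function(g, mode = 0) {
  if (!mode %in% 0:2) abort(paste0("unknown cluster mode: ", mode))
  ids <- g$nodes$nr_id
  lens <- setNames(g$nodes$length, ids)
  adj <- adjacency_list(ids, g$edges)
  assign <- switch(as.character(mode),
    "1" = cluster_components(ids, g$edges),
    "0" = cluster_set_cover(ids, adj, lens),
    "2" = cluster_greedy_incremental(ids, adj, lens)
  )
  # renumber clusters densely by first appearance in node order
  tibble(nr_id = ids, cluster = match(assign, unique(assign)))
}

adjacency_list <- function(ids, edges) {
  adj <- setNames(vector("list", length(ids)), ids)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      f <- edges$from[k]; t <- edges$to[k]
      if (f == t) next
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
    adj <- purrr::map(adj, unique)
  }
  adj
}

cluster_components <- function(ids, edges) {
  ig <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = ids)
  )
  memb <- igraph::components(ig)$membership
  unname(memb[ids])
}

cluster_set_cover <- function(ids, adj, lens) {
  uncovered <- setNames(rep(TRUE, length(ids)), ids)
  assign <- setNames(integer(length(ids)), ids)
  cl <- 0L
  while (any(uncovered)) {
    cand <- names(uncovered)[uncovered]
    gain <- purrr::map_int(cand, function(id) {
      1L + sum(uncovered[adj[[id]]])
    })
    ord <- order(-gain, -lens[cand], cand)
    center <- cand[ord[1]]
    members <- c(center, adj[[center]][uncovered[adj[[center]]]])
    cl <- cl + 1L
    assign[members] <- cl
    uncovered[members] <- FALSE
  }
  unname(assign[ids])
}

cluster_greedy_incremental <- function(ids, adj, lens) {
  assign <- setNames(integer(length(ids)), ids)
  ord <- ids[order(-lens[ids], ids)]
  cl <- 0L
  for (id in ord) {
    if (assign[id] != 0L) next
    cl <- cl + 1L
    free <- adj[[id]][assign[adj[[id]]] == 0L]
    assign[c(id, free)] <- cl
  }
  unname(assign[ids])
}

#' Cascaded clustering
#'
#' Clusters at strict thresholds first, then repeatedly re-clusters cluster
#' representatives at progressively relaxed thresholds, merging their
#' clusters, until the target thresholds are reached. Step `i` of `n` uses
#' `min_seq_id + (0.9 - min_seq_id) * (n - i) / n` (and coverage
#' interpolated from 0.95 the same way); with `cluster_steps = 1` this is
#' identical to a single [build_graph()] + [cluster_graph()] pass.
#' Representatives are each cluster's longest member (ties by smallest id).
#'
#' @inheritParams build_graph
#' @return A tibble with columns `nr_id` and `cluster` partitioning `nr`.
#' @export
cascade_cluster <- function(nr, params = cluster_params(),
                            scheme = scoring_scheme(), cache = NULL) {
  if (nrow(nr) == 0) abort("cannot cluster an empty set")
  n_steps <- params$cluster_steps
  part <- setNames(seq_len(nrow(nr)), nr$nr_id)
  lens <- setNames(nchar(nr$protein), nr$nr_id)
  for (i in seq_len(n_steps)) {
    frac <- (n_steps - i) / n_steps
    step <- params
    step$min_seq_id <- params$min_seq_id + (0.9 - params$min_seq_id) * frac
    step$coverage <- params$coverage + (0.95 - params$coverage) * frac
    reps <- vapply(split(names(part), part), function(mem) {
      mem[order(-lens[mem], mem)][1]
    }, character(1))
    sub <- nr[match(reps, nr$nr_id), ]
    g <- build_graph(sub, step, scheme, cache)
    cl <- cluster_graph(g, params$cluster_mode)
    rep_cluster <- setNames(cl$cluster, cl$nr_id)
    # clusters whose representatives co-clustered are unified
    old_to_new <- setNames(rep_cluster[reps], names(reps))
    part <- setNames(unname(old_to_new[as.character(part)]), names(part))
  }
  tibble(nr_id = nr$nr_id,
         cluster = match(part[nr$nr_id], unique(part[nr$nr_id])))
}

#' Merge phams by iterative profile-sequence search
#'
#' For each pham a position-specific profile is built from a center-star
#' alignment around the pham representative, then aligned against every
#' nonredundant sequence. A hit to a sequence of a different pham that
#' passes identity (against the profile consensus), bidirectional coverage
#' (profile columns and sequence) and E-value thresholds adds a pham-pham
#' edge; passing sequences are also attached to the profile for the next
#' iteration. After `num_iterations` the pham-level graph is interpreted by
#' the cluster mode. Phams only ever merge, never split, so the result is a
#' coarsening of the input partition.
#'
#' @param partition A tibble with columns `nr_id`, `cluster` (stage-1 phams).
#' @inheritParams build_graph
#' @return A tibble with columns `nr_id` and `cluster`.
#' @export
profile_merge <- function(partition, nr, params = cluster_params(
                            min_seq_id = 0.15, coverage = 0.60),
                          scheme = scoring_scheme(), cache = NULL) {
  stopifnot(all(partition$nr_id %in% nr$nr_id))
  seqs <- setNames(nr$protein, nr$nr_id)
  db_size <- sum(nchar(seqs))
  clusters <- sort(unique(partition$cluster))
  members <- split(partition$nr_id, partition$cluster)
  seq_cluster <- setNames(partition$cluster, partition$nr_id)
  active <- members
  edges <- tibble(from = character(), to = character())
  prof_len <- setNames(rep(0L, length(clusters)), as.character(clusters))

  for (iter in seq_len(params$num_iterations)) {
    attach_next <- active
    for (cl in as.character(clusters)) {
      mem <- active[[cl]]
      mseqs <- seqs[mem]
      center <- which(mem == representative_by_similarity(
        mem, mseqs, scheme, cache))
      msa <- center_star_msa(mseqs, center = center, scheme = scheme,
                             cache = cache)
      prof <- build_profile(msa, scheme)
      prof_len[[cl]] <- prof$length
      targets <- profile_candidates(prof, seqs, params$sensitivity)
      for (id in targets) {
        st <- profile_align(prof, seqs[[id]], scheme, db_size = db_size)
        pass <- st$identity >= params$min_seq_id &&
          min(st$coverage_query, st$coverage_target) >= params$coverage &&
          st$evalue <= params$evalue
        if (!pass) next
        other <- as.character(seq_cluster[[id]])
        if (other != cl) {
          edges <- bind_rows(edges, tibble(from = cl, to = other))
        }
        if (!id %in% attach_next[[cl]]) {
          attach_next[[cl]] <- c(attach_next[[cl]], id)
        }
      }
    }
    active <- attach_next
  }
  edges <- distinct(edges)
  g <- homology_graph(
    tibble(nr_id = as.character(clusters),
           length = unname(prof_len[as.character(clusters)])),
    edges
  )
  merged <- cluster_graph(g, params$cluster_mode)
  super <- setNames(merged$cluster, merged$nr_id)
  out_cluster <- unname(super[as.character(partition$cluster)])
  tibble(nr_id = partition$nr_id,
         cluster = match(out_cluster, unique(out_cluster)))
}

profile_candidates <- function(prof, seqs, sensitivity, k = 5L) {
  ids <- names(seqs)
  if (sensitivity >= 7) return(ids)
  cons <- prof$consensus
  if (nchar(cons) < k) return(ids)
  words <- unique(substring(cons, 1:(nchar(cons) - k + 1), k:nchar(cons)))
  keep <- vapply(seqs, function(s) {
    any(vapply(words, function(w) grepl(w, s, fixed = TRUE), logical(1)))
  }, logical(1))
  ids[keep]
}

# highest mean global similarity to the other members; singleton: itself;
# ties by longest sequence then smallest id
representative_by_similarity <- function(ids, seqs, scheme, cache = NULL) {
  if (length(ids) == 1) return(ids[1])
  sim <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      st <- global_align(seqs[[i]], seqs[[j]], scheme, cache = cache)
      sim[i, j] <- sim[j, i] <- st$similarity
    }
  }
  mean_sim <- (rowSums(sim) - 1) / (length(ids) - 1)
  lens <- nchar(seqs)
  ids[order(-mean_sim, -lens, ids)][1]
}

#' Assemble phams from gene tables
#'
#' The full pipeline: deduplicate exact-identical proteins, cascade-cluster
#' the nonredundant set over the homology graph, optionally merge remote
#' homolog phams with the profile-sequence stage, then expand clusters back
#' to all gene copies. Pham ids are assigned by descending size with ties
#' broken by smallest member gene id; each pham's representative is the
#' member with the highest average similarity to all other members.
#'
#' @param genes A gene table from [read_genome()]/[read_genomes()] (or a
#'   list of such tables, which are row-bound).
#' @param params Stage-1 (sequence-sequence) [cluster_params()].
#' @param profile_params Stage-2 (profile-sequence) [cluster_params()].
#' @param skip_profile If `TRUE`, bypass the profile-sequence merge stage.
#' @param scheme A [scoring_scheme()].
#' @param cache An [alignment_cache()]; defaults to a fresh one.
#' @return An object of class `pham_set` with elements `members` (tibble:
#'   `pham_id`, `gene_id`, `genome_id`, `protein`, `annotation`), `phams`
#'   (tibble: `pham_id`, `n_genes`, `representative`), `nr`,
#'   `nr_partition`, `params`, `profile_params`, `skip_profile`.
#' @export
assemble_phams <- function(genes, params = cluster_params(),
                           profile_params = cluster_params(
                             min_seq_id = 0.15, coverage = 0.60),
                           skip_profile = FALSE,
                           scheme = scoring_scheme(),
                           cache = alignment_cache()) {
  if (is.list(genes) && !is.data.frame(genes)) genes <- list_rbind(genes)
  if (!is.data.frame(genes) || nrow(genes) == 0) {
    abort("assemble_phams requires a non-empty gene table")
  }
  if (!"genome_id" %in% names(genes)) genes$genome_id <- "genome"
  if (!"annotation" %in% names(genes)) genes$annotation <- ""
  nr <- deduplicate(genes)
  part <- cascade_cluster(nr, params, scheme, cache)
  if (!skip_profile) {
    part <- profile_merge(part, nr, profile_params, scheme, cache)
  }
  expanded <- expand_clusters(part, nr)
  sizes <- expanded |>
    group_by(.data$cluster) |>
    summarise(n_genes = n(), min_gene = min(.data$gene_id),
              .groups = "drop") |>
    arrange(desc(.data$n_genes), .data$min_gene) |>
    mutate(pham_id = row_number())
  members <- expanded |>
    inner_join(sizes[, c("cluster", "pham_id")], by = "cluster") |>
    inner_join(genes[, c("gene_id", "genome_id", "protein", "annotation")],
               by = "gene_id") |>
    arrange(.data$pham_id, .data$gene_id) |>
    select("pham_id", "gene_id", "genome_id", "protein", "annotation")
  reps <- members |>
    group_by(.data$pham_id) |>
    summarise(representative = pham_representative_id(
      .data$gene_id, .data$protein, scheme, cache), .groups = "drop")
  phams <- sizes |>
    select("pham_id", "n_genes") |>
    inner_join(reps, by = "pham_id") |>
    arrange(.data$pham_id)
  structure(
    list(members = members, phams = phams, nr = nr, nr_partition = part,
         params = params, profile_params = profile_params,
         skip_profile = skip_profile, scheme = scheme),
    class = "pham_set"
  )
}

# representative over gene copies: similarity matrix computed once on the
# distinct sequences, then per-gene means weighted by copy number (identical
# copies contribute similarity 1 to each other)
pham_representative_id <- function(gene_ids, proteins, scheme, cache) {
  n <- length(gene_ids)
  if (n == 1) return(gene_ids[1])
  useqs <- unique(proteins)
  k <- length(useqs)
  sim <- matrix(1, k, k)
  if (k > 1) {
    for (i in seq_len(k)) {
      for (j in seq_len(i - 1L)) {
        st <- global_align(useqs[i], useqs[j], scheme, cache = cache)
        sim[i, j] <- sim[j, i] <- st$similarity
      }
    }
  }
  counts <- tabulate(match(proteins, useqs), nbins = k)
  seq_of <- match(proteins, useqs)
  # sum over other genes of similarity; own copy excluded (similarity 1)
  mean_sim <- (as.numeric(sim %*% counts)[seq_of] - 1) / (n - 1)
  lens <- nchar(proteins)
  gene_ids[order(-mean_sim, -lens, gene_ids)][1]
}

#' @export
print.pham_set <- function(x, ...) {
  orph <- sum(x$phams$n_genes == 1)
  cat("<pham_set> ", nrow(x$phams), " phams over ", nrow(x$members),
      " genes (", orph, " orphams)\n", sep = "")
  invisible(x)
}
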