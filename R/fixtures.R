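#' Specification for a synthetic planted-truth fixture
#'
#' Describes a deterministic synthetic dataset: protein families derived
#' from random ancestors at controlled mean pairwise identity, unrelated
#' singletons (orphams), and optional adversarial "traps" (a domain-chain
#' pair sharing only a local domain, an intein-interrupted family, a short
#' fragment under the 60% length rule). Defaults are the package's standard
#' test world: 5 families of 8 members at identities
#' 0.9/0.7/0.5/0.4/0.35 plus 10 orphams.
#'
#' @param n_families Number of planted families.
#' @param members_per_family Members per family (also the genome count:
#'   member j of every family is placed in genome j).
#' @param identities Target mean pairwise identity per family (recycled).
#' @param n_orphams Number of unrelated singleton genes.
#' @param ancestor_length Family ancestor length in residues.
#' @param traps Character subset of
#'   `c("domain_chain", "intein", "short_fragment")`.
#' @param seed Integer seed; the same spec and seed give byte-identical
#'   output.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_families = 5, members_per_family = 8,
                         identities = c(0.9, 0.7, 0.5, 0.4, 0.35),
                         n_orphams = 10, ancestor_length = 150,
                         traps = character(0), seed = 1L) {
  bad <- setdiff(traps, c("domain_chain", "intein", "short_fragment"))
  if (length(bad)) abort(paste0("unknown trap: ", bad[1]))
  structure(
    list(n_families = n_families, members_per_family = members_per_family,
         identities = rep_len(identities, n_families),
         n_orphams = n_orphams, ancestor_length = ancestor_length,
         traps = traps, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

random_protein <- function(len) {
  bg <- blosum62_background()
  paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = "")
}

# per ancestor residue, the distribution of substitutions over the other 19
# residues, proportional to exp(BLOSUM62 score) for realism
substitution_dists <- function() {
  if (is.null(.phamr$subdist)) {
    B <- blosum62()[AA_STANDARD, AA_STANDARD]
    .phamr$subdist <- purrr::map(setNames(AA_STANDARD, AA_STANDARD),
                                 function(a) {
      w <- exp(B[a, ])
      w[a] <- 0
      w / sum(w)
    })
  }
  .phamr$subdist
}

# retention probability m so that two members independently derived from
# the ancestor show mean pairwise identity t, accounting for the chance
# that two substitutions at the same site coincide
solve_retention <- function(t) {
  dists <- substitution_dists()
  bg <- blosum62_background()
  coll <- sum(bg * purrr::map_dbl(dists, ~ sum(.x^2)))
  disc <- coll^2 - (1 + coll) * (coll - t)
  (coll + sqrt(disc)) / (1 + coll)
}

#' Generate one synthetic protein family
#'
#' Draws a random ancestor and derives `n` members by BLOSUM62-biased point
#' substitutions (plus rare short indels) calibrated so the mean pairwise
#' identity lands within about 5 points of the target. `identity = 1`
#' yields identical copies.
#'
#' @param ancestor_length Ancestor length in residues.
#' @param n Number of members.
#' @param identity Target mean pairwise identity in (0, 1].
#' @param seed Integer seed.
#' @param indel_prob Per-member probability of carrying one 1-3 residue
#'   indel (suppressed when `identity = 1`).
#' @return Character vector of `n` member proteins.
#' @export
generate_family <- function(ancestor_length, n, identity, seed,
                            indel_prob = 0.15) {
  if (identity <= 0 || identity > 1) abort("identity must lie in (0, 1]")
  with_seed(seed, {
    anc <- seq_chars(random_protein(ancestor_length))
    if (identity == 1) {
      return(rep(paste(anc, collapse = ""), n))
    }
    m <- solve_retention(identity)
    dists <- substitution_dists()
    bg <- blosum62_background()
    purrr::map_chr(seq_len(n), function(i) {
      keep <- stats::runif(ancestor_length) < m
      member <- anc
      for (pos in which(!keep)) {
        d <- dists[[anc[pos]]]
        member[pos] <- sample(names(d), 1, prob = d)
      }
      if (stats::runif(1) < indel_prob && length(member) > 10) {
        k <- sample(1:3, 1)
        at <- sample(2:(length(member) - k - 1), 1)
        if (stats::runif(1) < 0.5) {
          member <- member[-(at:(at + k - 1))]
        } else {
          ins <- sample(names(bg), k, replace = TRUE, prob = bg)
          member <- append(member, ins, after = at)
        }
      }
      paste(member, collapse = "")
    })
  })
}

derive_member <- function(anc, m, dists) {
  keep <- stats::runif(length(anc)) < m
  out <- anc
  for (pos in which(!keep)) {
    d <- dists[[anc[pos]]]
    out[pos] <- sample(names(d), 1, prob = d)
  }
  out
}

#' Generate two remote sub-families from a common ancestor
#'
#' Builds the classic remote-homology scenario: one ancestor, two diverged
#' base sequences, and `n_per` members derived from each base. Within-group
#' identity is high while the between-group identity sits below typical
#' sequence-sequence clustering thresholds, so stage 1 separates the groups
#' and the profile-sequence stage is needed to merge them.
#'
#' @param ancestor_length Ancestor length in residues.
#' @param n_per Members per sub-family.
#' @param within_identity Target mean pairwise identity inside a group.
#' @param between_identity Target identity between the two base sequences.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_id`, `protein`, `family`
#'   (`subfamA`/`subfamB`).
#' @export
generate_remote_subfamilies <- function(ancestor_length = 200, n_per = 4,
                                        within_identity = 0.85,
                                        between_identity = 0.28,
                                        seed = 1L) {
  with_seed(seed, {
    dists <- substitution_dists()
    anc <- seq_chars(random_protein(ancestor_length))
    mb <- solve_retention(between_identity)
    bases <- list(derive_member(anc, mb, dists),
                  derive_member(anc, mb, dists))
    mw <- solve_retention(within_identity)
    rows <- purrr::imap(bases, function(base, b) {
      tibble(
        gene_id = sprintf("SF%s%02d", LETTERS[b], seq_len(n_per)),
        protein = purrr::map_chr(seq_len(n_per), function(i) {
          paste(derive_member(base, mw, dists), collapse = "")
        }),
        family = paste0("subfam", LETTERS[b])
      )
    })
    list_rbind(rows)
  })
}

#' Generate the adversarial trap proteins for a fixture
#'
#' `domain_chain`: two otherwise unrelated backbones sharing one planted
#' domain covering under 40% of their length (they must not co-cluster at
#' coverage thresholds of 0.7 or above). `intein`: a family in which some
#' members carry a 150-residue insertion; intein-containing and
#' intein-free homologs should still co-cluster (the base length of 250
#' residues keeps members above the 60% length rule). `short_fragment`: a
#' member truncated below 60% of its family's length, which the audit must
#' flag as a length false positive.
#'
#' @param spec A [fixture_spec()] (its `traps` field selects which traps
#'   to build; `seed` feeds the generator).
#' @return A tibble with columns `gene_id`, `protein`, `family`, `trap`,
#'   `annotation`.
#' @export
generate_traps <- function(spec) {
  out <- list()
  if ("domain_chain" %in% spec$traps) {
    parts <- with_seed(spec$seed + 101L, {
      list(domain = random_protein(60), b1 = random_protein(200),
           b2 = random_protein(200))
    })
    p1 <- paste0(substr(parts$b1, 1, 100), parts$domain,
                 substr(parts$b1, 101, 200))
    p2 <- paste0(substr(parts$b2, 1, 100), parts$domain,
                 substr(parts$b2, 101, 200))
    out$dchain <- tibble(
      gene_id = c("TRAPDCA", "TRAPDCB"), protein = c(p1, p2),
      family = c("trap_chain_A", "trap_chain_B"), trap = "domain_chain",
      annotation = "hypothetical protein"
    )
  }
  if ("intein" %in% spec$traps) {
    base <- generate_family(250, 6, 0.8, spec$seed + 202L, indel_prob = 0)
    intein <- with_seed(spec$seed + 203L, random_protein(150))
    withins <- purrr::map_chr(base[1:3], function(p) {
      paste0(substr(p, 1, 125), intein, substr(p, 126, nchar(p)))
    })
    out$intein <- tibble(
      gene_id = sprintf("INTEIN%02d", 1:6),
      protein = c(withins, base[4:6]),
      family = "trap_intein", trap = "intein",
      annotation = "terminase, large subunit"
    )
  }
  if ("short_fragment" %in% spec$traps) {
    donor <- generate_family(spec$ancestor_length, 1, 0.9,
                             spec$seed + 304L, indel_prob = 0)
    frag <- substr(donor, 1, floor(0.45 * nchar(donor)))
    out$frag <- tibble(
      gene_id = "TRAPFRAG", protein = frag, family = "family01",
      trap = "short_fragment", annotation = ""
    )
  }
  if (length(out) == 0) {
    return(tibble(gene_id = character(), protein = character(),
                  family = character(), trap = character(),
                  annotation = character()))
  }
  list_rbind(out)
}

# annotation variants cycled over family members so synonym normalization
# has something to do
family_labels <- function(i) {
  sets <- list(
    c("portal", "Portal", "portal protein"),
    c("terminase, large subunit", "TerL", "large terminase"),
    c("minor tail protein", "Minor Tail Protein", ""),
    c("major capsid protein", "Major capsid protein", "MCP"),
    c("lysin B", "LysB", "lysin b")
  )
  sets[[(i - 1L) %% length(sets) + 1L]]
}

#' Generate a fixture in memory
#'
#' Builds the gene table and ground-truth table described by a
#' [fixture_spec()] without touching the filesystem. Genomes receive one
#' member of each family plus orphams round-robin; trap genes are appended
#' to the earliest genomes. Coordinates place genes 100 nt apart on a
#' synthetic genome.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `genes` (a [read_genome()]-shaped tibble) and
#'   `truth` (tibble: `gene_id`, `genome_id`, `family`, `trap`).
#' @export
generate_fixture <- function(spec) {
  n_gen <- spec$members_per_family
  genome_ids <- sprintf("SYNPHG%02d", seq_len(n_gen))
  rows <- list()
  for (i in seq_len(spec$n_families)) {
    fam <- generate_family(spec$ancestor_length, spec$members_per_family,
                           spec$identities[i], spec$seed + i)
    labels <- rep_len(family_labels(i), spec$members_per_family)
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = sprintf("F%02dM%02d", i, seq_len(spec$members_per_family)),
      protein = fam,
      genome_id = genome_ids,
      family = sprintf("family%02d", i),
      trap = NA_character_,
      annotation = labels
    )
  }
  if (spec$n_orphams > 0) {
    orph <- with_seed(spec$seed + 500L, {
      lens <- sample(120:200, spec$n_orphams, replace = TRUE)
      purrr::map_chr(lens, random_protein)
    })
    rows[[length(rows) + 1L]] <- tibble(
      gene_id = sprintf("ORPH%02d", seq_len(spec$n_orphams)),
      protein = orph,
      genome_id = genome_ids[(seq_len(spec$n_orphams) - 1L) %% n_gen + 1L],
      family = sprintf("orpham%02d", seq_len(spec$n_orphams)),
      trap = NA_character_,
      annotation = "hypothetical protein"
    )
  }
  traps <- generate_traps(spec)
  if (nrow(traps)) {
    traps$genome_id <- genome_ids[(seq_len(nrow(traps)) - 1L) %% n_gen + 1L]
    rows[[length(rows) + 1L]] <- traps
  }
  genes <- list_rbind(rows)
  # lay genes onto each genome, 100 nt apart
  genes <- genes |>
    group_by(.data$genome_id) |>
    arrange(.data$gene_id, .by_group = TRUE) |>
    mutate(
      .cds_len = 3L * (nchar(.data$protein) + 1L),
      stop = 100L + cumsum(.data$.cds_len + 100L) - 100L,
      start = .data$stop - .data$.cds_len + 1L,
      strand = "+"
    ) |>
    ungroup() |>
    select(-".cds_len")
  truth <- genes |> select("gene_id", "genome_id", "family", "trap")
  genes <- genes |>
    mutate(name = .data$genome_id, translation_table = 11L) |>
    select("gene_id", "genome_id", "name", "start", "stop", "strand",
           "protein", "annotation", "translation_table")
  list(genes = genes, truth = truth)
}

# one deterministic, non-initiator codon per residue (so translating the
# span reproduces the protein exactly, including the first residue)
REVERSE_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATC", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT", X = "NNN"
)

reverse_translate <- function(protein) {
  paste0(paste(REVERSE_CODON[seq_chars(protein)], collapse = ""), "TAA")
}

#' Write a fixture to disk as GenBank, FASTA and a truth table
#'
#' Emits one GenBank flat file and one protein FASTA per genome, plus
#' `truth.tsv` (`gene_id`, `genome_id`, `family`, `trap`). Coding spans are
#' reverse-translated with non-initiator codons so that translating the
#' span reproduces the planted protein exactly; `/translation` qualifiers
#' are included unless `include_translations = FALSE`.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @param include_translations Write `/translation` qualifiers.
#' @return Invisibly, a list with `genes`, `truth` and the written paths.
#' @export
write_fixture <- function(spec, outdir, include_translations = TRUE) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort(paste0("cannot create ", outdir))
  fx <- generate_fixture(spec)
  paths <- character(0)
  for (g in unique(fx$genes$genome_id)) {
    sub <- fx$genes |> filter(.data$genome_id == g) |> arrange(.data$start)
    gb <- file.path(outdir, paste0(g, ".gbk"))
    writeLines(render_genbank(g, sub, spec$seed, include_translations), gb)
    fa <- file.path(outdir, paste0(g, ".faa"))
    writeLines(unlist(purrr::pmap(sub, function(gene_id, protein,
                                              annotation, ...) {
      c(paste0(">", gene_id, if (nzchar(annotation))
        paste0(" ", annotation) else ""), protein)
    })), fa)
    paths <- c(paths, gb, fa)
  }
  truth_path <- file.path(outdir, "truth.tsv")
  readr::write_tsv(fx$truth, truth_path)
  invisible(c(fx, list(paths = c(paths, truth_path))))
}

render_genbank <- function(genome_id, genes, seed, include_translations) {
  total_len <- max(genes$stop) + 100L
  spacers <- with_seed(seed + 900L + nchar(genome_id), {
    paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
          collapse = "")
  })
  seq_nt <- spacers
  for (k in seq_len(nrow(genes))) {
    cds <- reverse_translate(genes$protein[k])
    substr(seq_nt, genes$start[k], genes$stop[k]) <- cds
  }
  head <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   PHG 01-JAN-2026",
            genome_id, total_len),
    sprintf("DEFINITION  Synthetic phage genome %s.", genome_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", total_len)
  )
  feats <- unlist(purrr::pmap(genes, function(gene_id, start, stop,
                                              protein, annotation, ...) {
    q <- c(
      sprintf("     CDS             %d..%d", start, stop),
      sprintf("                     /locus_tag=\"%s\"", gene_id),
      if (nzchar(annotation))
        sprintf("                     /product=\"%s\"", annotation),
      "                     /transl_table=11"
    )
    if (include_translations) {
      txt <- paste0("/translation=\"", protein, "\"")
      starts <- seq(1, nchar(txt), by = 58)
      tr <- substring(txt, starts, pmin(starts + 57, nchar(txt)))
      q <- c(q, paste0("                     ", tr))
    }
    q
  }))
  origin <- c("ORIGIN")
  pos <- seq(1, nchar(seq_nt), by = 60)
  for (p in pos) {
    chunk <- substr(seq_nt, p, min(p + 59, nchar(seq_nt)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    origin <- c(origin, sprintf("%9d %s", p,
                                paste(tolower(groups), collapse = " ")))
  }
  c(head, feats, origin, "//")
}
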