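#' Translate a coding sequence with the bacterial genetic code
#'
#' Uses NCBI translation table 11 (Bacterial, Archaeal and Plant Plastid) by
#' default. The terminal stop codon is removed, the first codon is rendered
#' as `M` when it is a table-11 initiator (`ATG`/`GTG`/`TTG`), and ambiguous
#' codons are rendered `X`.
#'
#' @param nt Nucleotide string; length must be a multiple of 3.
#' @param table NCBI genetic-code table id (default 11).
#' @return The protein string, without a terminal stop.
#' @examples
#' translate_cds("ATGGCTTAA")
#' translate_cds("GTGGCTTAA") # initiator GTG renders as M
#' @export
translate_cds <- function(nt, table = 11) {
  nt <- str_to_upper(nt)
  nt <- gsub("U", "T", nt, fixed = TRUE)
  if (nchar(nt) == 0 || nchar(nt) %% 3 != 0) {
    abort("coding sequence length must be a positive multiple of 3")
  }
  code <- Biostrings::getGeneticCode(as.character(table))
  codons <- substring(nt, seq(1, nchar(nt), by = 3), seq(3, nchar(nt), by = 3))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  if (codons[1] %in% c("ATG", "GTG", "TTG")) aa[1] <- "M"
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    abort("internal stop codon: malformed coding sequence")
  }
  paste(aa, collapse = "")
}

#' Parse a genome file into a gene table
#'
#' Reads a GenBank flat file (possibly multi-record) or a FASTA file of
#' protein or nucleotide coding sequences, returning one row per
#' protein-coding gene. Coordinates are 1-based inclusive, as in GenBank
#' flat files. For GenBank CDS features a `/translation` qualifier is used
#' verbatim when present; otherwise the protein is translated from the
#' feature's nucleotide span (compound `join()` locations are concatenated
#' in feature order and reverse-complemented on the minus strand). CDS
#' features whose translation contains an internal stop, is shorter than 10
#' residues, or cannot be obtained at all are skipped with a warning. FASTA
#' headers contribute the first whitespace-delimited token as `gene_id` and
#' the remainder as the annotation.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"genbank"`, `"fasta-aa"`, `"fasta-nt"`.
#' @return A tibble with columns `gene_id`, `genome_id`, `name`, `start`,
#'   `stop`, `strand`, `protein`, `annotation`, `translation_table`, ordered
#'   by start coordinate where coordinates exist.
#' @export
read_genome <- function(path, format = c("auto", "genbank", "fasta-aa",
                                         "fasta-nt")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("cannot read input file: ", path))
  if (format == "auto") format <- sniff_format(path)
  genes <- switch(format,
    genbank = parse_genbank(path),
    `fasta-aa` = parse_fasta(path, translate = FALSE),
    `fasta-nt` = parse_fasta(path, translate = TRUE)
  )
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id in ", path))
  }
  genes
}

#' @rdname read_genome
#' @param paths Character vector of genome file paths.
#' @export
read_genomes <- function(paths, format = "auto") {
  out <- purrr::map(paths, read_genome, format = format) |> list_rbind()
  if (anyDuplicated(out$gene_id)) {
    abort("gene_id values collide across input files")
  }
  out
}

sniff_format <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(first)]
  if (length(first) == 0) abort(paste0("empty input file: ", path))
  if (grepl("^LOCUS", first[1])) return("genbank")
  if (grepl("^>", first[1])) {
    body <- paste(first[!grepl("^>", first)], collapse = "")
    letters <- unique(strsplit(str_to_upper(body), "")[[1]])
    nt_only <- all(letters %in% c("A", "C", "G", "T", "U", "N"))
    return(if (nt_only) "fasta-nt" else "fasta-aa")
  }
  abort(paste0("unrecognized input format: ", path))
}

parse_fasta <- function(path, translate) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no records in FASTA file: ", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  ann <- ifelse(grepl("\\s", headers),
                str_squish(sub("^\\S+\\s+", "", headers)), "")
  genome_id <- sub("\\.(fa|faa|fna|fasta|ffn)$", "",
                   basename(path), ignore.case = TRUE)
  seqs <- str_to_upper(as.character(set))
  keep <- rep(TRUE, length(seqs))
  prots <- character(length(seqs))
  for (i in seq_along(seqs)) {
    if (translate) {
      p <- tryCatch(translate_cds(seqs[i]), error = function(e) NULL)
      if (is.null(p)) {
        warn(paste0("skipping record ", ids[i], ": ", "untranslatable CDS"))
        keep[i] <- FALSE
        next
      }
      prots[i] <- p
    } else {
      prots[i] <- clean_protein(seqs[i])
    }
    if (nchar(prots[i]) < 10) {
      warn(paste0("skipping record ", ids[i], ": protein shorter than 10 aa"))
      keep[i] <- FALSE
    }
  }
  tibble(
    gene_id = ids[keep], genome_id = genome_id, name = genome_id,
    start = NA_integer_, stop = NA_integer_, strand = NA_character_,
    protein = prots[keep], annotation = ann[keep], translation_table = 11L
  )
}

# strip terminal stop, uppercase, collapse non-standard residues onto X
clean_protein <- function(p) {
  p <- sub("\\*$", "", str_to_upper(p))
  gsub(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), "X", p)
}

parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) abort(paste0("not a GenBank flat file: ", path))
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- purrr::map2(starts, ends, function(s, e) {
    parse_genbank_record(lines[s:e])
  })
  list_rbind(recs)
}

parse_genbank_record <- function(lines) {
  locus <- str_squish(sub("^LOCUS\\s+", "", lines[1]))
  genome_id <- strsplit(locus, "\\s+")[[1]][1]
  def_i <- grep("^DEFINITION", lines)
  name <- if (length(def_i)) {
    str_squish(sub("^DEFINITION\\s*", "", lines[def_i[1]]))
  } else genome_id

  feat_i <- grep("^FEATURES", lines)
  origin_i <- grep("^ORIGIN", lines)
  end_feat <- if (length(origin_i)) origin_i[1] - 1L else length(lines)
  seq_nt <- ""
  if (length(origin_i)) {
    body <- lines[(origin_i[1] + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq_nt <- str_to_upper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (length(feat_i) == 0) {
    warn(paste0("GenBank record ", genome_id, " has no FEATURES table"))
    return(empty_gene_table())
  }
  flines <- lines[(feat_i[1] + 1L):end_feat]
  # feature keys start at column 6; qualifier/continuation lines at column 22
  key_rows <- grep("^ {5}\\S", flines)
  if (length(key_rows) == 0) return(empty_gene_table())
  key_ends <- c(key_rows[-1] - 1L, length(flines))
  genes <- list()
  cds_n <- 0L
  for (k in seq_along(key_rows)) {
    block <- flines[key_rows[k]:key_ends[k]]
    key <- str_squish(substr(block[1], 6, 20))
    if (key != "CDS") next
    cds_n <- cds_n + 1L
    g <- parse_cds_block(block, genome_id, name, seq_nt, cds_n)
    if (!is.null(g)) genes[[length(genes) + 1L]] <- g
  }
  if (length(genes) == 0) return(empty_gene_table())
  out <- list_rbind(genes)
  if (all(!is.na(out$start))) out <- arrange(out, .data$start)
  out
}

empty_gene_table <- function() {
  tibble(
    gene_id = character(), genome_id = character(), name = character(),
    start = integer(), stop = integer(), strand = character(),
    protein = character(), annotation = character(),
    translation_table = integer()
  )
}

parse_cds_block <- function(block, genome_id, name, seq_nt, cds_n) {
  txt <- paste(str_squish(block), collapse = "\n")
  parts <- strsplit(txt, "\n/", fixed = TRUE)[[1]]
  loc_str <- str_squish(sub("^CDS\\s+", "", gsub("\n", "", parts[1])))
  quals <- list()
  for (p in parts[-1]) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) {
      quals[[str_squish(p)]] <- TRUE
    } else {
      key <- substr(p, 1, eq - 1)
      val <- substr(p, eq + 1, nchar(p))
      val <- gsub("\"", "", val)
      joined <- if (key == "translation") gsub("\n", "", val)
                else gsub("\n", " ", val)
      quals[[key]] <- str_squish(joined)
    }
  }
  loc <- parse_location(loc_str)
  table <- suppressWarnings(as.integer(quals[["transl_table"]] %||% 11L))
  if (is.na(table)) table <- 11L
  gene_id <- quals[["locus_tag"]] %||% quals[["gene"]] %||%
    paste0(genome_id, "_CDS_", cds_n)
  annotation <- quals[["product"]] %||% quals[["function"]] %||% ""

  protein <- quals[["translation"]]
  if (!is.null(protein)) {
    protein <- clean_protein(gsub(" ", "", protein))
  } else if (nzchar(seq_nt) && !is.null(loc)) {
    nt <- extract_span(seq_nt, loc)
    if (is.null(nt)) {
      warn(paste0("skipping ", gene_id, ": location outside sequence"))
      return(NULL)
    }
    protein <- tryCatch(translate_cds(nt, table), error = function(e) NULL)
    if (is.null(protein)) {
      warn(paste0("skipping ", gene_id,
                  ": internal stop codon or malformed CDS"))
      return(NULL)
    }
  } else {
    warn(paste0("skipping ", gene_id,
                ": no /translation and no nucleotide sequence"))
    return(NULL)
  }
  if (nchar(protein) < 10 || grepl("\\*", protein)) {
    warn(paste0("skipping ", gene_id,
                ": translation shorter than 10 aa or contains stops"))
    return(NULL)
  }
  tibble(
    gene_id = gene_id, genome_id = genome_id, name = name,
    start = loc$start %||% NA_integer_, stop = loc$stop %||% NA_integer_,
    strand = loc$strand %||% NA_character_, protein = protein,
    annotation = annotation, translation_table = table
  )
}

# GenBank location strings: a..b, complement(...), join(...), <a..>b.
# Exons are kept in feature order; `complement` anywhere marks the minus
# strand and the concatenated span is reverse-complemented as a whole.
parse_location <- function(loc) {
  minus <- grepl("complement", loc, fixed = TRUE)
  ranges <- gregexpr("[<>]?\\d+\\.\\.[<>]?\\d+|\\b\\d+\\b", loc)[[1]]
  if (ranges[1] < 0) return(NULL)
  pieces <- regmatches(loc, gregexpr("\\d+\\.\\.\\d+|\\b\\d+\\b",
                                     gsub("[<>]", "", loc)))[[1]]
  exons <- purrr::map(pieces, function(p) {
    xs <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (length(xs) == 1) xs <- c(xs, xs)
    xs
  })
  list(
    exons = exons,
    start = min(purrr::map_int(exons, 1)),
    stop = max(purrr::map_int(exons, 2)),
    strand = if (minus) "-" else "+"
  )
}

extract_span <- function(seq_nt, loc) {
  n <- nchar(seq_nt)
  segs <- purrr::map_chr(loc$exons, function(e) {
    if (e[2] > n || e[1] < 1) return(NA_character_)
    substr(seq_nt, e[1], e[2])
  })
  if (anyNA(segs)) return(NULL)
  nt <- paste(segs, collapse = "")
  if (identical(loc$strand, "-")) nt <- revcomp(nt)
  nt
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Collapse genes onto their nonredundant protein sequences
#'
#' Exact full-string match on the uppercased protein defines redundancy;
#' every gene appears in exactly one entry. Entry ids are assigned in order
#' of first appearance, making the mapping deterministic.
#'
#' @param genes A gene table as returned by [read_genome()] (columns
#'   `gene_id` and `protein` are required).
#' @return A tibble with columns `nr_id`, `protein`, `gene_ids`
#'   (list-column), `n_copies`.
#' @export
deduplicate <- function(genes) {
  if (nrow(genes) == 0) {
    return(tibble(nr_id = character(), protein = character(),
                  gene_ids = list(), n_copies = integer()))
  }
  if (anyDuplicated(genes$gene_id)) abort("gene_id values must be unique")
  if (any(!nzchar(genes$protein))) abort("empty protein sequence in input")
  genes |>
    mutate(protein = str_to_upper(.data$protein),
           .first = match(.data$protein, .data$protein)) |>
    group_by(.data$.first, .data$protein) |>
    summarise(gene_ids = list(.data$gene_id), .groups = "drop") |>
    arrange(.data$.first) |>
    mutate(nr_id = sprintf("nr%05d", row_number()),
           n_copies = lengths(.data$gene_ids)) |>
    select("nr_id", "protein", "gene_ids", "n_copies")
}

#' Expand a clustering of nonredundant sequences back to gene copies
#'
#' The inverse of [deduplicate()]: genes sharing an identical sequence always
#' land in the same pham, and the total gene count is conserved.
#'
#' @param clusters A tibble with columns `nr_id` and `cluster` forming a
#'   partition of the nonredundant set.
#' @param nr A nonredundant set from [deduplicate()].
#' @return A tibble with columns `cluster` and `gene_id`.
#' @export
expand_clusters <- function(clusters, nr) {
  if (!all(clusters$nr_id %in% nr$nr_id)) {
    abort("cluster refers to nr_id absent from the nonredundant set")
  }
  if (!all(nr$nr_id %in% clusters$nr_id)) {
    abort("partition does not cover the nonredundant set")
  }
  if (anyDuplicated(clusters$nr_id)) {
    abort("nr_id assigned to more than one cluster")
  }
  nr |>
    inner_join(clusters, by = "nr_id") |>
    select("cluster", "gene_ids") |>
    tidyr::unnest_longer("gene_ids") |>
    rename(gene_id = "gene_ids")
}
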