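#' Canonical ORF identifier
#'
#' Identifiers follow the convention `<code>_<strain>_<local id>`, all lower
#' case, where `<code>` is a four-letter species abbreviation and `<strain>`
#' a positive integer distinguishing strains of the same species. Identifiers
#' already carrying the prefix are returned unchanged (idempotent).
#'
#' @param species_code four-letter species code.
#' @param strain_index positive integer strain index.
#' @param local_id local identifier (e.g. the FASTA record id).
#' @return character vector of canonical ORF ids.
#' @export
canonical_orf_id <- function(species_code, strain_index, local_id) {
  species_code <- check_species_code(species_code)
  strain_index <- assert_count(strain_index, "strain_index", min = 1L)
  prefix <- sprintf("%s_%d_", species_code, strain_index)
  id <- tolower(local_id)
  has <- startsWith(id, prefix)
  id[!has] <- paste0(prefix, id[!has])
  id
}

check_species_code <- function(species_code) {
  assert_scalar_chr(species_code, "species_code")
  species_code <- tolower(species_code)
  if (nchar(species_code) != 4L || grepl("[^a-z]", species_code))
    stop2("species_code must be exactly 4 letters, got '", species_code, "'")
  species_code
}

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

# Uppercase, strip terminal stop '*', map any non-standard residue to X.
sanitize_protein <- function(seqs, ids) {
  seqs <- toupper(seqs)
  seqs <- gsub("\\*", "", seqs)
  bad <- grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "X]"), seqs)
  if (any(bad)) {
    warning(sum(bad), " sequence(s) contained non-standard residues; mapped to X (e.g. ",
            ids[which(bad)[1L]], ")", call. = FALSE)
    pat <- paste0("[^", paste(AA_STANDARD, collapse = ""), "X]")
    seqs[bad] <- gsub(pat, "X", seqs[bad])
  }
  if (any(!nzchar(seqs)))
    stop2("empty protein sequence after sanitising: ", ids[which(!nzchar(seqs))[1L]])
  seqs
}

read_gene_order <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE) ||
      any(startsWith(readLines(path, n = 1L), "##gff-version"))) {
    return(read_gene_order_gff3(path))
  }
  tab <- read_tsv(path)
  need <- c("orf_id", "scaffold_id")
  if (!all(need %in% names(tab)))
    stop2("gene-order table must have columns orf_id and scaffold_id: ", path)
  if (is.null(tab$rank_hint)) tab$rank_hint <- seq_len(nrow(tab))
  if (is.null(tab$strand)) tab$strand <- "."
  tab[, c("orf_id", "scaffold_id", "rank_hint", "strand")]
}

# Minimal GFF3 reader: rows of type "gene" (all rows if none), genes ranked by
# start coordinate per seqid; ORF id taken from the ID attribute.
read_gene_order_gff3 <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path)
    d <- as.data.frame(gr)
    if ("type" %in% names(d) && any(d$type == "gene")) d <- d[d$type == "gene", ]
    ids <- if (!is.null(d$ID)) as.character(d$ID) else as.character(d$Name)
    tab <- data.frame(orf_id = ids, scaffold_id = as.character(d$seqnames),
                      rank_hint = d$start, strand = as.character(d$strand),
                      stringsAsFactors = FALSE)
  } else {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
    f <- strsplit(ln, "\t", fixed = TRUE)
    f <- f[vapply(f, length, 1L) >= 9L]
    typ <- vapply(f, `[[`, "", 3L)
    if (any(typ == "gene")) f <- f[typ == "gene"]
    ids <- vapply(f, function(x) {
      m <- regmatches(x[9L], regexec("ID=([^;]+)", x[9L]))[[1L]]
      if (length(m) == 2L) m[2L] else NA_character_
    }, "")
    if (anyNA(ids)) stop2("GFF3 rows without an ID attribute in ", path)
    tab <- data.frame(orf_id = ids,
                      scaffold_id = vapply(f, `[[`, "", 1L),
                      rank_hint = as.integer(vapply(f, `[[`, "", 4L)),
                      strand = vapply(f, `[[`, "", 7L),
                      stringsAsFactors = FALSE)
  }
  tab$strand[!tab$strand %in% c("+", "-")] <- "."
  tab[order(tab$scaffold_id, tab$rank_hint), ]
}

new_genome_record <- function(species_code, strain_index, wgd_status, orfs, seqs) {
  structure(list(species_code = species_code, strain_index = strain_index,
                 wgd_status = wgd_status, orfs = orfs, seqs = seqs),
            class = "genome_record")
}

#' Load one genome into a genome record
#'
#' Reads a protein FASTA and a gene-order table (headered TSV with columns
#' `orf_id`, `scaffold_id`, `rank_hint`, `strand`, or a GFF3 file whose gene
#' rows are ranked by start coordinate per seqid) and produces a
#' `genome_record`: every FASTA record becomes an ORF with a canonical
#' identifier and a 0-based ordinal position along its scaffold. ORFs present
#' in the FASTA but absent from the order table are assigned, in input order,
#' to a per-genome `"unplaced"` scaffold. Stop-codon asterisks are stripped
#' and non-standard residues are mapped to X with a warning.
#'
#' @param proteome_fasta path to a protein FASTA file.
#' @param gene_order_table path to a gene-order TSV or GFF3 file.
#' @param species_code exactly four letters (case-insensitive).
#' @param strain_index positive integer.
#' @param wgd_status `"pre"` or `"post"`: position of the species relative to
#'   the whole-genome duplication.
#' @return an object of class `genome_record`.
#' @export
load_genome <- function(proteome_fasta, gene_order_table, species_code,
                        strain_index, wgd_status = c("pre", "post")) {
  wgd_status <- match.arg(wgd_status)
  species_code <- check_species_code(species_code)
  strain_index <- assert_count(strain_index, "strain_index", min = 1L)

  aa <- Biostrings::readAAStringSet(proteome_fasta)
  fasta_ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(fasta_ids))
    stop2("duplicate FASTA id: ", fasta_ids[duplicated(fasta_ids)][1L])
  seqs <- sanitize_protein(as.character(aa), fasta_ids)
  canon <- canonical_orf_id(species_code, strain_index, fasta_ids)
  names(seqs) <- canon

  if (length(canon) == 0L) {
    orfs <- data.frame(orf_id = character(), scaffold_id = character(),
                       ordinal = integer(), strand = character(),
                       length = integer(), stringsAsFactors = FALSE)
    return(new_genome_record(species_code, strain_index, wgd_status, orfs, seqs))
  }

  order_tab <- if (file.exists(gene_order_table) && file.size(gene_order_table) > 0)
    read_gene_order(gene_order_table)
  else
    data.frame(orf_id = character(), scaffold_id = character(),
               rank_hint = integer(), strand = character(), stringsAsFactors = FALSE)
  order_tab$orf_id <- canonical_orf_id(species_code, strain_index, order_tab$orf_id)
  known <- order_tab$orf_id %in% canon
  if (any(!known)) {
    warning(sum(!known), " gene-order row(s) with no matching FASTA record dropped",
            call. = FALSE)
    order_tab <- order_tab[known, , drop = FALSE]
  }
  if (anyDuplicated(order_tab$orf_id))
    stop2("duplicate orf_id in gene-order table: ",
          order_tab$orf_id[duplicated(order_tab$orf_id)][1L])

  placed <- order_tab[order(order_tab$scaffold_id, order_tab$rank_hint), ]
  unplaced_ids <- setdiff(canon, placed$orf_id)
  if (length(unplaced_ids))
    placed <- rbind(placed,
                    data.frame(orf_id = unplaced_ids, scaffold_id = "unplaced",
                               rank_hint = seq_along(unplaced_ids), strand = ".",
                               stringsAsFactors = FALSE))
  placed$ordinal <- stats::ave(seq_len(nrow(placed)), placed$scaffold_id,
                               FUN = seq_along) - 1L
  placed$strand[!placed$strand %in% c("+", "-")] <- "."

  orfs <- data.frame(orf_id = placed$orf_id, scaffold_id = placed$scaffold_id,
                     ordinal = placed$ordinal, strand = placed$strand,
                     length = nchar(seqs[placed$orf_id]),
                     stringsAsFactors = FALSE, row.names = NULL)
  orfs <- orfs[order(orfs$scaffold_id, orfs$ordinal), ]
  rownames(orfs) <- NULL
  new_genome_record(species_code, strain_index, wgd_status, orfs, seqs[orfs$orf_id])
}

#' Compile genome records into a multi-genome ORF database
#'
#' @param genomes list of `genome_record` objects with pairwise-distinct
#'   (species_code, strain_index).
#' @return an object of class `genome_db` with fields `genomes`, `orf_table`
#'   (one row per ORF: orf_id, species_code, strain_index, scaffold_id,
#'   ordinal, strand, length, wgd_status), `seqs` (named character vector) and
#'   `total_orf_count`.
#' @export
compile_db <- function(genomes) {
  if (!is.list(genomes))
    stop2("genomes must be a list of genome_record objects")
  genomes <- unname(genomes)
  if (length(genomes)) {
    keys <- vapply(genomes, function(g) paste(g$species_code, g$strain_index), "")
    if (anyDuplicated(keys))
      stop2("duplicate (species_code, strain_index): ", keys[duplicated(keys)][1L])
  }
  tabs <- lapply(genomes, function(g) {
    if (nrow(g$orfs) == 0L) return(NULL)
    cbind(g$orfs[, c("orf_id", "scaffold_id", "ordinal", "strand", "length")],
          species_code = g$species_code, strain_index = g$strain_index,
          wgd_status = g$wgd_status, stringsAsFactors = FALSE)
  })
  orf_table <- do.call(rbind, c(tabs, list(
    data.frame(orf_id = character(), scaffold_id = character(),
               ordinal = integer(), strand = character(), length = integer(),
               species_code = character(), strain_index = integer(),
               wgd_status = character(), stringsAsFactors = FALSE))))
  rownames(orf_table) <- NULL
  if (anyDuplicated(orf_table$orf_id))
    stop2("orf_id collision across genomes: ",
          orf_table$orf_id[duplicated(orf_table$orf_id)][1L])
  seqs <- unlist(lapply(genomes, `[[`, "seqs"))
  if (is.null(seqs)) seqs <- character(0)
  names(seqs) <- orf_table$orf_id
  structure(list(genomes = genomes, orf_table = orf_table, seqs = seqs,
                 total_orf_count = nrow(orf_table)),
            class = "genome_db")
}

#' @export
print.genome_db <- function(x, ...) {
  cat("Multi-genome ORF database\n")
  cat("  genomes:", length(x$genomes),
      sprintf("(%d pre-WGD, %d post-WGD)\n",
              sum(vapply(x$genomes, `[[`, "", "wgd_status") == "pre"),
              sum(vapply(x$genomes, `[[`, "", "wgd_status") == "post")))
  cat("  total ORFs:", x$total_orf_count, "\n")
  invisible(x)
}

db_lookup <- function(db, orf_id) {
  i <- match(orf_id, db$orf_table$orf_id)
  if (is.na(i)) stop2("unknown orf_id: ", orf_id)
  db$orf_table[i, ]
}

#' Neighbouring genes of a query ORF
#'
#' Returns up to `k` genes upstream (signed offsets -k..-1) and `k` genes
#' downstream (+1..+k) of the query on the same scaffold of the same genome,
#' truncated at scaffold ends; neighbourhoods never cross scaffolds and the
#' query itself (offset 0) is never included. Strand is ignored.
#'
#' @param db a `genome_db`.
#' @param orf_id query ORF id (must be present in `db`).
#' @param k window half-width in genes (>= 1); the reference analysis uses 15.
#' @return data.frame with columns `orf_id`, `offset`, ordered by offset.
#' @export
get_neighbour_ids <- function(db, orf_id, k = 15L) {
  k <- assert_count(k, "k", min = 1L)
  q <- db_lookup(db, orf_id)
  tab <- db$orf_table
  same <- tab$species_code == q$species_code &
    tab$strain_index == q$strain_index & tab$scaffold_id == q$scaffold_id
  nb <- tab[same, c("orf_id", "ordinal")]
  nb$offset <- nb$ordinal - q$ordinal
  nb <- nb[nb$offset != 0L & abs(nb$offset) <= k, c("orf_id", "offset")]
  nb <- nb[order(nb$offset), ]
  rownames(nb) <- NULL
  nb
}

#' Write a genome database as per-genome FASTA + gene-order tables
#'
#' Inverse of [load_genome()]/[compile_db()]: reloading the written files
#' reproduces the database (id set, ordinals, sequences).
#'
#' @param db a `genome_db`.
#' @param dir output directory (created if missing).
#' @return invisibly, a data.frame listing the files written per genome.
#' @export
write_genome_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- lapply(db$genomes, function(g) {
    base <- sprintf("%s_%d", g$species_code, g$strain_index)
    fa <- file.path(dir, paste0(base, ".faa"))
    tsv <- file.path(dir, paste0(base, ".order.tsv"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(g$seqs), fa)
    ord <- g$orfs[order(g$orfs$scaffold_id, g$orfs$ordinal), ]
    write_tsv(data.frame(orf_id = ord$orf_id, scaffold_id = ord$scaffold_id,
                         rank_hint = ord$ordinal, strand = ord$strand),
              tsv)
    data.frame(species_code = g$species_code, strain_index = g$strain_index,
               wgd_status = g$wgd_status, fasta = fa, order = tsv,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, files))
}

#' Write the consolidated database manifest
#'
#' @param db a `genome_db`.
#' @param path output TSV path.
#' @export
write_db_manifest <- function(db, path) {
  tab <- db$orf_table[, c("orf_id", "species_code", "strain_index",
                          "scaffold_id", "ordinal", "strand", "length")]
  write_tsv(tab, path)
}
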