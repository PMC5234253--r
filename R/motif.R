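IUPAC_DNA <- list(A = "A", C = "C", G = "G", T = "T",
                  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                  W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                  B = c("C", "G", "T"), D = c("A", "G", "T"),
                  H = c("A", "C", "T"), V = c("A", "C", "G"),
                  N = c("A", "C", "G", "T"))

#' Parse a degenerate promoter-motif specification
#'
#' Grammar: plain IUPAC letters (N = any base, H = not G, D = not C, ...),
#' parenthesised alternatives such as `(G/C)`, and variable-length runs such
#' as `(T)4-6` (four to six Ts) or `(T)4`. Examples of recognised binding-site
#' patterns: the Haa1 acetic-acid-responsive element `(G/C)(A/C)GG(G/C)G` and
#' the Cup2 sites `TC(T)4-6GCTG` and `HTHNNGCTGD`.
#'
#' @param spec motif specification text.
#' @param name optional motif name (defaults to the spec text).
#' @return an object of class `degenerate_motif`: list of elements, each with
#'   `bases` (allowed base set), `min` and `max` repeat counts.
#' @export
parse_motif <- function(spec, name = spec) {
  assert_scalar_chr(spec, "motif spec")
  s <- toupper(gsub("\\s", "", spec))
  # tolerate underscore-delimited repeat counts, e.g. (T)_4-6_
  s <- gsub("_", "", s)
  elements <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      close <- regexpr(")", substr(s, i, n), fixed = TRUE)
      if (close < 0) stop2("unclosed '(' at position ", i, " in motif '", spec, "'")
      inner <- substr(s, i + 1L, i + close - 2L)
      alts <- strsplit(inner, "/", fixed = TRUE)[[1L]]
      if (!length(alts) || any(!alts %in% names(IUPAC_DNA)))
        stop2("invalid alternative set '(", inner, ")' at position ", i,
              " in motif '", spec, "'")
      bases <- sort(unique(unlist(IUPAC_DNA[alts])))
      i <- i + close
      rep_m <- regmatches(substr(s, i, n),
                          regexec("^([0-9]+)(-([0-9]+))?", substr(s, i, n)))[[1L]]
      if (length(rep_m) && nzchar(rep_m[1L])) {
        lo <- as.integer(rep_m[2L])
        hi <- if (nzchar(rep_m[4L])) as.integer(rep_m[4L]) else lo
        if (lo < 1L || lo > hi)
          stop2("invalid repeat range at position ", i, " in motif '", spec, "'")
        i <- i + nchar(rep_m[1L])
      } else {
        lo <- hi <- 1L
      }
      elements[[length(elements) + 1L]] <- list(bases = bases, min = lo, max = hi)
    } else if (ch %in% names(IUPAC_DNA)) {
      elements[[length(elements) + 1L]] <-
        list(bases = IUPAC_DNA[[ch]], min = 1L, max = 1L)
      i <- i + 1L
    } else {
      stop2("unexpected character '", ch, "' at position ", i,
            " in motif '", spec, "'")
    }
  }
  if (!length(elements)) stop2("empty motif spec")
  structure(list(name = name, spec = spec, elements = elements),
            class = "degenerate_motif")
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat(sprintf("Degenerate motif '%s' (%s): %d elements, match length %d-%d\n",
              x$name, x$spec, length(x$elements),
              sum(vapply(x$elements, `[[`, 1L, "min")),
              sum(vapply(x$elements, `[[`, 1L, "max"))))
  invisible(x)
}

#' The binding-site motifs of the Haa1/Cup2 transcription-factor family
#'
#' The Haa1 acetic-acid-responsive element and the two alternative Cup2
#' (Ace1) binding-site descriptions reported in the literature; the two Cup2
#' motifs are scanned and reported separately.
#'
#' @return named list of `degenerate_motif`s.
#' @export
motif_catalog <- function() {
  list(haa1_acre = parse_motif("(G/C)(A/C)GG(G/C)G", "haa1_acre"),
       cup2_trun = parse_motif("TC(T)4-6GCTG", "cup2_trun"),
       cup2_hth = parse_motif("HTHNNGCTGD", "cup2_hth"))
}

# Expand variable-run elements into all concrete per-position base-set lists.
motif_expansions <- function(motif) {
  reps <- lapply(motif$elements, function(e) e$min:e$max)
  grid <- expand.grid(reps, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(g) {
    sets <- list()
    for (k in seq_along(motif$elements))
      sets <- c(sets, rep(list(motif$elements[[k]]$bases), grid[g, k]))
    sets
  })
}

scan_one_strand <- function(chars, sets) {
  L <- length(sets)
  n <- length(chars)
  if (n < L) return(integer(0))
  ok <- matrix(FALSE, n - L + 1L, L)
  for (p in seq_len(L))
    ok[, p] <- chars[p:(n - L + p)] %in% sets[[p]]
  which(rowSums(ok) == L)
}

#' Scan a DNA sequence for a degenerate motif
#'
#' Reports every match at every offset; overlapping matches are all reported
#' and variable-run motifs report each feasible run length as a separate hit.
#' Coordinates are 0-based half-open on the forward strand; minus-strand hits
#' are matches of the motif to the reverse complement, with `matched_text`
#' given in motif orientation. An `N` in the sequence matches no motif
#' element.
#'
#' @param seq DNA text over A, C, G, T, N (case-insensitive).
#' @param motif a `degenerate_motif` (or a spec string, parsed on the fly).
#' @param both_strands scan the reverse complement too (default TRUE).
#' @return data.frame with columns `motif_name`, `start`, `end`, `strand`,
#'   `matched_text`.
#' @export
scan_sequence <- function(seq, motif, both_strands = TRUE) {
  if (is.character(motif)) motif <- parse_motif(motif)
  empty <- data.frame(motif_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      matched_text = character(), stringsAsFactors = FALSE)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) stop2("seq must be a character scalar")
  seq <- toupper(seq)
  if (!nzchar(seq)) return(empty)
  if (grepl("[^ACGTN]", seq)) stop2("sequence must be over A, C, G, T, N")
  n <- nchar(seq)
  fwd <- strsplit(seq, "", fixed = TRUE)[[1L]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  rev_chars <- strsplit(rc, "", fixed = TRUE)[[1L]]

  rows <- list()
  for (sets in motif_expansions(motif)) {
    L <- length(sets)
    for (st in scan_one_strand(fwd, sets)) {
      rows[[length(rows) + 1L]] <- data.frame(
        motif_name = motif$name, start = st - 1L, end = st - 1L + L,
        strand = "+", matched_text = substr(seq, st, st + L - 1L),
        stringsAsFactors = FALSE)
    }
    if (both_strands) {
      for (st in scan_one_strand(rev_chars, sets)) {
        rows[[length(rows) + 1L]] <- data.frame(
          motif_name = motif$name, start = n - (st - 1L + L), end = n - (st - 1L),
          strand = "-", matched_text = substr(rc, st, st + L - 1L),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(empty)))
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Presence/absence calls of motifs in a promoter sequence
#'
#' @param seq promoter DNA sequence.
#' @param motifs list of `degenerate_motif`s (default: [motif_catalog()]).
#' @param both_strands scan both strands (default TRUE).
#' @return named logical vector: at least one hit per motif.
#' @export
classify_promoter <- function(seq, motifs = motif_catalog(),
                              both_strands = TRUE) {
  vapply(motifs, function(m) nrow(scan_sequence(seq, m, both_strands)) > 0L,
         TRUE)
}

#' Scan promoter sequences from a FASTA file
#'
#' @param fasta_path DNA FASTA of promoter regions.
#' @param motifs list of `degenerate_motif`s (default: [motif_catalog()]).
#' @param out_tsv optional path; when given, hits are written as BED-like TSV
#'   (seq_id, start, end, motif_name, strand), 0-based half-open.
#' @return data.frame of hits with a leading `seq_id` column.
#' @export
scan_promoter_fasta <- function(fasta_path, motifs = motif_catalog(),
                                out_tsv = NULL) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(dna))
  rows <- list()
  for (i in seq_along(dna)) {
    for (m in motifs) {
      h <- scan_sequence(as.character(dna[[i]]), m)
      if (nrow(h)) rows[[length(rows) + 1L]] <- cbind(seq_id = ids[i], h)
    }
  }
  out <- do.call(rbind, c(rows, list(
    data.frame(seq_id = character(), motif_name = character(),
               start = integer(), end = integer(), strand = character(),
               matched_text = character(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  if (!is.null(out_tsv))
    write_tsv(out[, c("seq_id", "start", "end", "motif_name", "strand")], out_tsv)
  out
}
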