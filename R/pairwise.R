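#' Alignment parameter set
#'
#' Bundles the scoring system used for local (Smith--Waterman) and global
#' (Needleman--Wunsch) protein alignments, together with the Karlin--Altschul
#' statistics used to convert raw local scores into e-values.
#'
#' Gap penalties are stored as positive magnitudes and applied as penalties.
#' Defaults are the classic blastp defaults for BLOSUM62 (gap open 11, gap
#' extend 1, word size 3, extension threshold 11) with the published gapped
#' Karlin--Altschul constants lambda = 0.267 and K = 0.041.
#'
#' @param substitution_matrix a named 20+ letter score matrix, or the name of
#'   a matrix shipped with Biostrings (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend non-negative gap penalty magnitudes; a gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param seed_word_size,seed_threshold word-seeding parameters recorded for
#'   provenance with externally produced hit tables.
#' @param ka_lambda,ka_k positive Karlin--Altschul parameters.
#' @param effective_db_letters optional positive integer; when set it replaces
#'   the subject length in the e-value search space.
#' @param report_ceiling permissive e-value ceiling for stored hits.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11, gap_extend = 1,
                             seed_word_size = 3L, seed_threshold = 11L,
                             ka_lambda = 0.267, ka_k = 0.041,
                             effective_db_letters = NULL,
                             report_ceiling = 10) {
  if (is.character(substitution_matrix)) {
    nm <- substitution_matrix
    e <- new.env()
    utils::data(list = nm, package = "Biostrings", envir = e)
    substitution_matrix <- get(nm, envir = e)
    attr(substitution_matrix, "matrix_name") <- nm
  }
  if (gap_open < 0 || gap_extend < 0)
    stop2("gap penalties are stored as non-negative magnitudes")
  if (ka_lambda <= 0 || ka_k <= 0)
    stop2("Karlin-Altschul lambda and K must be positive")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 seed_word_size = as.integer(seed_word_size),
                 seed_threshold = as.integer(seed_threshold),
                 ka_lambda = ka_lambda, ka_k = ka_k,
                 effective_db_letters = effective_db_letters,
                 report_ceiling = report_ceiling),
            class = "alignment_params")
}

check_seq_nonempty <- function(x, what) {
  assert_scalar_chr(x, what)
  if (!nzchar(x)) stop2(what, " must be non-empty")
  toupper(x)
}

# Column statistics of one pairwise alignment given the two gapped strings.
aln_stats <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1L]]
  sc <- strsplit(s, "", fixed = TRUE)[[1L]]
  len <- length(pc)
  gaps <- sum(pc == "-" | sc == "-")
  matches <- sum(pc == sc & pc != "-")
  list(identity_pct = 100 * matches / len,
       gap_pct = 100 * gaps / len,
       mismatch_pct = 100 * (len - matches - gaps) / len,
       aln_length = len)
}

#' Exact local protein alignment
#'
#' Optimal affine-gap Smith--Waterman alignment of two protein sequences.
#' Identity and gap percentages are computed over all alignment columns
#' (including gap columns), so identity + mismatch + gap percentages sum
#' to 100.
#'
#' @param a,b protein sequences (non-empty character scalars).
#' @param params an [alignment_params()] object.
#' @return list with `score`, `identity_pct`, `gap_pct`, `aln_length`.
#' @export
align_local <- function(a, b, params = alignment_params()) {
  a <- check_seq_nonempty(a, "a"); b <- check_seq_nonempty(b, "b")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  st <- aln_stats(as.character(Biostrings::alignedPattern(al)),
                  as.character(Biostrings::alignedSubject(al)))
  c(list(score = Biostrings::score(al)), st)
}

#' Global protein alignment statistics
#'
#' Optimal Needleman--Wunsch alignment (end gaps penalised). `scores` may be
#' an [alignment_params()] object or a simple scheme
#' `list(match =, mismatch =, gap_open =, gap_extend =)`.
#'
#' @param a,b protein sequences.
#' @param scores scoring scheme (see Details).
#' @return list with `score`, `identity_pct`, `gap_pct`, `mismatch_pct`,
#'   `aln_length`.
#' @export
align_global <- function(a, b, scores = alignment_params()) {
  a <- check_seq_nonempty(a, "a"); b <- check_seq_nonempty(b, "b")
  if (inherits(scores, "alignment_params")) {
    mat <- scores$substitution_matrix
    go <- scores$gap_open; ge <- scores$gap_extend
  } else {
    letters24 <- c(AA_STANDARD, "B", "J", "Z", "X")
    mat <- matrix(scores$mismatch, length(letters24), length(letters24),
                  dimnames = list(letters24, letters24))
    diag(mat) <- scores$match
    g <- abs(scores$gap %||% scores$gap_extend)
    go <- abs(scores$gap_open %||% 0); ge <- g
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = go, gapExtension = ge)
  st <- aln_stats(as.character(Biostrings::alignedPattern(al)),
                  as.character(Biostrings::alignedSubject(al)))
  c(list(score = Biostrings::score(al)), st)
}

#' Karlin--Altschul e-value for a local alignment score
#'
#' Standard closed form `E = K * m * n * exp(-lambda * S)`: strictly
#' decreasing in the score and strictly increasing in either sequence length.
#'
#' @param score raw local alignment score.
#' @param m,n lengths (>= 1) of the two sequences (or of the effective search
#'   space).
#' @param params an [alignment_params()] object supplying lambda and K.
#' @return the e-value (positive numeric).
#' @export
evalue_from_score <- function(score, m, n, params = alignment_params()) {
  if (params$ka_lambda <= 0 || params$ka_k <= 0)
    stop2("Karlin-Altschul lambda and K must be positive")
  if (any(m < 1) || any(n < 1)) stop2("m and n must be >= 1")
  if (any(!is.finite(score))) stop2("score must be finite")
  params$ka_k * m * n * exp(-params$ka_lambda * score)
}

# Unordered candidate pairs sharing at least one exact word of length w.
shared_word_pairs <- function(seqs, w) {
  n <- length(seqs)
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < w) return(character(0))
    unique(substring(s, 1:(L - w + 1L), w:L))
  })
  ids <- rep.int(seq_len(n), lengths(kmers))
  sp <- split(ids, unlist(kmers))
  sp <- sp[lengths(sp) >= 2L]
  if (!length(sp)) return(matrix(integer(0), ncol = 2L))
  keys <- unlist(lapply(sp, function(v) {
    cmb <- utils::combn(sort(v), 2L)
    cmb[1L, ] * (n + 1L) + cmb[2L, ]
  }), use.names = FALSE)
  keys <- sort(unique(keys))
  cbind(keys %/% (n + 1L), keys %% (n + 1L))
}

#' All-vs-all local alignment hit table
#'
#' Aligns every pair of ORFs in the database with exact affine-gap
#' Smith--Waterman, assigns Karlin--Altschul e-values, and reports hits for
#' all ordered pairs whose e-value passes the permissive report ceiling
#' (self-pairs excluded). With the default word prefilter, only pairs sharing
#' at least one exact `filter_word`-mer are aligned (a blast-style seeding
#' heuristic); set `filter_word = NULL` for exact mode over every pair.
#' Deterministic given the inputs.
#'
#' @param db a `genome_db`.
#' @param params an [alignment_params()] object.
#' @param filter_word integer word length for the shared-word prefilter, or
#'   `NULL` to align all pairs.
#' @return data.frame of class `pairwise_hits` with columns `query_id`,
#'   `subject_id`, `score`, `evalue`, `identity_pct`, `aln_length`, `gap_pct`.
#' @export
all_vs_all <- function(db, params = alignment_params(), filter_word = 5L) {
  if (db$total_orf_count == 0L) stop2("empty genome database")
  seqs <- db$seqs
  n <- length(seqs)
  empty <- data.frame(query_id = character(), subject_id = character(),
                      score = numeric(), evalue = numeric(),
                      identity_pct = numeric(), aln_length = integer(),
                      gap_pct = numeric(), stringsAsFactors = FALSE)
  if (n < 2L) return(structure(empty, class = c("pairwise_hits", "data.frame")))

  if (is.null(filter_word)) {
    cmb <- utils::combn(n, 2L)
    pairs <- cbind(cmb[1L, ], cmb[2L, ])
  } else {
    pairs <- shared_word_pairs(seqs, as.integer(filter_word))
  }
  if (nrow(pairs) == 0L) return(structure(empty, class = c("pairwise_hits", "data.frame")))

  lens <- nchar(seqs)
  out <- vector("list", n)
  aaset <- Biostrings::AAStringSet(seqs)
  for (j in sort(unique(pairs[, 2L]))) {
    is <- pairs[pairs[, 2L] == j, 1L]
    al <- Biostrings::pairwiseAlignment(
      aaset[is], aaset[[j]], type = "local",
      substitutionMatrix = params$substitution_matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    sc <- Biostrings::score(al)
    nn <- params$effective_db_letters %||% lens[j]
    ev <- evalue_from_score(sc, lens[is], nn, params)
    keep <- ev <= params$report_ceiling
    if (!any(keep)) next
    alk <- al[keep]
    len <- Biostrings::nchar(alk)           # alignment columns incl. gaps
    nm <- Biostrings::nmatch(alk)
    nmm <- Biostrings::nmismatch(alk)
    out[[j]] <- data.frame(
      query_id = names(seqs)[is[keep]], subject_id = names(seqs)[j],
      score = sc[keep], evalue = ev[keep],
      identity_pct = 100 * nm / len, aln_length = as.integer(len),
      gap_pct = 100 * (len - nm - nmm) / len,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  hits <- do.call(rbind, c(out[!vapply(out, is.null, TRUE)], list(empty)))
  # mirror to ordered pairs: stats are symmetric, e-value uses m*n either way
  rev <- hits
  rev$query_id <- hits$subject_id
  rev$subject_id <- hits$query_id
  hits <- rbind(hits, rev)
  hits <- hits[order(hits$query_id, hits$subject_id), ]
  rownames(hits) <- NULL
  structure(hits, class = c("pairwise_hits", "data.frame"))
}

#' Cross-group mean identity and gap statistics
#'
#' Arithmetic means of global-alignment identity and gap percentages over all
#' cross pairs A x B (identical ids excluded); when the two groups are the
#' same set, the mean is over unordered distinct pairs.
#'
#' @param groupA,groupB non-empty character vectors of ORF ids present in `db`.
#' @param db a `genome_db`.
#' @param scores scoring scheme for [align_global()].
#' @return list with `mean_identity_pct`, `mean_gap_pct`, `n_pairs`.
#' @export
group_identity_summary <- function(groupA, groupB, db,
                                   scores = alignment_params()) {
  if (!length(groupA) || !length(groupB)) stop2("groups must be non-empty")
  missing <- setdiff(c(groupA, groupB), names(db$seqs))
  if (length(missing)) stop2("unknown orf_id: ", missing[1L])
  if (setequal(groupA, groupB)) {
    g <- sort(unique(groupA))
    if (length(g) < 2L) stop2("within-group summary needs >= 2 members")
    cmb <- utils::combn(g, 2L)
    pairs <- data.frame(a = cmb[1L, ], b = cmb[2L, ], stringsAsFactors = FALSE)
  } else {
    pairs <- expand.grid(a = groupA, b = groupB, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, ]
  }
  st <- mapply(function(a, b) {
    r <- align_global(db$seqs[[a]], db$seqs[[b]], scores)
    c(r$identity_pct, r$gap_pct)
  }, pairs$a, pairs$b)
  list(mean_identity_pct = mean(st[1L, ]), mean_gap_pct = mean(st[2L, ]),
       n_pairs = nrow(pairs))
}

#' Write a hit table in blast outfmt-6-compatible TSV
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. Coordinate and gap-open columns not tracked
#' by the internal engine are written as 0; the raw score is written in the
#' bitscore column.
#'
#' @param hits a `pairwise_hits` data.frame.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  mism <- round(hits$aln_length * (100 - hits$identity_pct - hits$gap_pct) / 100)
  tab <- data.frame(qseqid = hits$query_id, sseqid = hits$subject_id,
                    pident = round(hits$identity_pct, 2),
                    length = hits$aln_length, mismatch = as.integer(mism),
                    gapopen = 0L, qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                    evalue = hits$evalue, bitscore = hits$score)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a blast outfmt-6 tabular hit table
#'
#' Accepts standard 12-column blastp `-outfmt 6` output (no header); extra
#' columns are ignored. Self-hits are dropped.
#'
#' @param path path to the tabular file.
#' @return a `pairwise_hits` data.frame.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           quote = "")
  if (ncol(tab) < 12L) stop2("expected >= 12 outfmt-6 columns in ", path)
  hits <- data.frame(query_id = as.character(tab[[1L]]),
                     subject_id = as.character(tab[[2L]]),
                     score = as.numeric(tab[[12L]]),
                     evalue = as.numeric(tab[[11L]]),
                     identity_pct = as.numeric(tab[[3L]]),
                     aln_length = as.integer(tab[[4L]]),
                     gap_pct = NA_real_, stringsAsFactors = FALSE)
  hits <- hits[hits$query_id != hits$subject_id, ]
  hits$evalue[hits$evalue <= 0] <- .Machine$double.xmin
  rownames(hits) <- NULL
  structure(hits, class = c("pairwise_hits", "data.frame"))
}
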