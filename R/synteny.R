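singleton_label <- function(orf_id) paste0("singleton:", orf_id)

is_singleton_label <- function(label) startsWith(label, "singleton:")

#' Label a neighbourhood window with similarity-cluster families
#'
#' Attaches the sequence-clustering family label to every neighbour in a raw
#' window from [get_neighbour_ids()]. Neighbours absent from the clustering
#' receive a unique singleton label and can therefore never form a shared
#' pair.
#'
#' @param window_raw data.frame with columns `orf_id`, `offset`.
#' @param clustering named character vector mapping ORF ids to family labels
#'   (see [cluster_all()]).
#' @param query_id optional query id recorded as an attribute.
#' @return data.frame of class `neighbourhood_window` with columns `orf_id`,
#'   `offset`, `family_label`.
#' @export
label_window <- function(window_raw, clustering, query_id = NULL) {
  lab <- if (length(clustering)) unname(clustering[window_raw$orf_id])
         else rep(NA_character_, nrow(window_raw))
  miss <- is.na(lab)
  lab[miss] <- singleton_label(window_raw$orf_id[miss])
  w <- data.frame(orf_id = window_raw$orf_id, offset = window_raw$offset,
                  family_label = lab, stringsAsFactors = FALSE)
  w <- w[order(w$offset), ]
  rownames(w) <- NULL
  attr(w, "query_id") <- query_id
  class(w) <- c("neighbourhood_window", "data.frame")
  w
}

#' Extract and label the neighbourhood window of a query gene
#'
#' Convenience wrapper around [get_neighbour_ids()] and [label_window()].
#'
#' @param db a `genome_db`.
#' @param query_id query ORF id.
#' @param clustering named family-label vector.
#' @param k window half-width in genes (default 15).
#' @return a `neighbourhood_window`.
#' @export
neighbourhood_window <- function(db, query_id, clustering, k = 15L) {
  label_window(get_neighbour_ids(db, query_id, k), clustering, query_id)
}

#' Shared neighbour pairs between two windows
#'
#' One pair is reported for every non-singleton family label present in both
#' windows. When a label occurs several times within a window, the instance
#' with the smallest absolute offset is used; ties are broken toward the
#' upstream (negative) instance for determinism.
#'
#' @param wa,wb `neighbourhood_window`s of two distinct query genes.
#' @return data.frame with columns `family_label`, `offset_a`, `offset_b`,
#'   `neighbour_id_a`, `neighbour_id_b`.
#' @export
shared_pairs <- function(wa, wb) {
  closest <- function(w) {
    keep <- !is_singleton_label(w$family_label)
    w <- w[keep, , drop = FALSE]
    if (!nrow(w)) return(w)
    o <- order(w$family_label, abs(w$offset), w$offset)
    w <- w[o, , drop = FALSE]
    w[!duplicated(w$family_label), , drop = FALSE]
  }
  a <- closest(wa); b <- closest(wb)
  common <- intersect(a$family_label, b$family_label)
  ia <- match(common, a$family_label); ib <- match(common, b$family_label)
  out <- data.frame(family_label = common,
                    offset_a = a$offset[ia], offset_b = b$offset[ib],
                    neighbour_id_a = a$orf_id[ia], neighbour_id_b = b$orf_id[ib],
                    stringsAsFactors = FALSE)
  out[order(out$family_label), , drop = FALSE]
}

#' Score a synteny edge from its shared neighbour pairs
#'
#' Edge strength combines the three lines of neighbourhood evidence as a sum
#' of per-pair products `c * s * r`, each factor in (0, 1]:
#' \itemize{
#'   \item closeness `c = 1 / max(|offset_a|, |offset_b|)` -- neighbours
#'     adjacent to both queries weigh most;
#'   \item neighbour sequence similarity
#'     `s = min(1, -log10(pair_evalue) / 60)` (clamped at 0), with `s = 1`
#'     when no e-value is available for the pair;
#'   \item cluster rarity `r = 2 / cluster_size` -- a two-member family, the
#'     smallest that can match, scores 1; matches from large families are
#'     likelier by chance and are down-weighted.
#' }
#' The edge is flagged `strong` when the strength reaches `strong_cutoff`.
#'
#' @param pairs data.frame from [shared_pairs()].
#' @param cluster_sizes named integer vector: family label -> cluster size
#'   (must be >= 2 for every matched label).
#' @param strong_cutoff strength threshold for a strong edge (default 0.3,
#'   calibrated on the bundled simulator so that within-sub-lineage edges are
#'   strong and cross-WGD / pre-vs-post edges are not).
#' @param pair_evalues optional numeric vector (one per row of `pairs`;
#'   `NA` = not available).
#' @return list of class `synteny_edge` with `shared`, `strength`, `strong`.
#' @export
score_edge <- function(pairs, cluster_sizes, strong_cutoff = 0.3,
                       pair_evalues = NULL) {
  if (nrow(pairs) == 0L) {
    return(structure(list(shared = pairs, strength = 0, strong = FALSE),
                     class = "synteny_edge"))
  }
  sizes <- cluster_sizes[pairs$family_label]
  if (anyNA(sizes) || any(sizes < 2L))
    stop2("matched family label with cluster size < 2: ",
          pairs$family_label[which(is.na(sizes) | sizes < 2L)[1L]])
  cc <- 1 / pmax(abs(pairs$offset_a), abs(pairs$offset_b))
  if (is.null(pair_evalues)) pair_evalues <- rep(NA_real_, nrow(pairs))
  ss <- ifelse(is.na(pair_evalues), 1,
               pmin(1, pmax(0, -log10(pair_evalues)) / 60))
  rr <- 2 / as.numeric(sizes)
  strength <- sum(cc * ss * rr)
  structure(list(shared = cbind(pairs, closeness = cc, similarity = ss,
                                rarity = rr),
                 strength = strength, strong = strength >= strong_cutoff),
            class = "synteny_edge")
}

# e-value of the stored network edge joining a and b, or NA.
edge_evalue <- function(net, a, b) {
  if (is.null(net)) return(NA_real_)
  lut <- attr(net, "evalue_lut")
  if (is.null(lut)) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    i <- which(net$edges$node_a == lo & net$edges$node_b == hi)
    return(if (length(i)) net$edges$evalue[i[1L]] else NA_real_)
  }
  e <- get0(paste(pmin(a, b), pmax(a, b), sep = "\r"), envir = lut,
            ifnotfound = NA_real_)
  e
}

# Hash lookup for repeated edge_evalue queries.
with_evalue_lut <- function(net) {
  if (is.null(net) || !nrow(net$edges)) return(net)
  lut <- new.env(parent = emptyenv(), size = nrow(net$edges))
  keys <- paste(net$edges$node_a, net$edges$node_b, sep = "\r")
  for (i in seq_along(keys)) assign(keys[i], net$edges$evalue[i], envir = lut)
  attr(net, "evalue_lut") <- lut
  net
}

#' Reconstruct ortholog/ohnolog sub-lineages from gene neighbourhoods
#'
#' Computes all-pairs synteny edges among the query genes, flags strong edges,
#' and partitions the queries into sub-lineages as the connected components of
#' the strong-edge subgraph. Each sub-lineage is annotated with the majority
#' role of its members. Shared-neighbour e-values are looked up in the
#' similarity network when available; pairs missing from the network (e.g.
#' filtered by the sweep ceiling) are aligned on demand when `db` and `params`
#' are supplied.
#'
#' @param db a `genome_db`.
#' @param queries character vector (>= 2) of query ORF ids.
#' @param clustering named family-label vector over all ORFs (see
#'   [cluster_all()]).
#' @param k neighbourhood half-width in genes (default 15).
#' @param params [alignment_params()] for on-demand neighbour alignments.
#' @param net optional `similarity_network` for e-value lookup.
#' @param strong_cutoff strong-edge threshold (default 0.3, simulator
#'   calibrated; see [score_edge()]).
#' @param roles optional data.frame from [assign_roles()].
#' @return an object of class `lineage_graph` with `nodes` (orf_id,
#'   wgd_status, role, sublineage), `edges` (query_a, query_b, n_shared,
#'   strength, strong) and `sublineage_roles` (majority role per sub-lineage).
#' @export
build_lineage_graph <- function(db, queries, clustering, k = 15L,
                                params = alignment_params(), net = NULL,
                                strong_cutoff = 0.3, roles = NULL) {
  queries <- unique(as.character(queries))
  if (length(queries) < 2L) stop2("need >= 2 query genes")
  windows <- lapply(queries, function(q) neighbourhood_window(db, q, clustering, k))
  names(windows) <- queries
  cluster_sizes <- table(clustering)
  net <- with_evalue_lut(net)

  nq <- length(queries)
  pair_idx <- utils::combn(nq, 2L)
  shared <- lapply(seq_len(ncol(pair_idx)), function(pp)
    shared_pairs(windows[[pair_idx[1L, pp]]], windows[[pair_idx[2L, pp]]]))

  # resolve neighbour-pair e-values: network lookup first, then one batched
  # on-demand alignment pass for pairs the hit table does not cover
  evs <- lapply(shared, function(sp) {
    if (!nrow(sp)) return(numeric(0))
    vapply(seq_len(nrow(sp)), function(r)
      edge_evalue(net, sp$neighbour_id_a[r], sp$neighbour_id_b[r]), 1)
  })
  need <- unique(do.call(rbind, c(lapply(seq_along(shared), function(pp) {
    sp <- shared[[pp]]
    if (!nrow(sp)) return(NULL)
    miss <- is.na(evs[[pp]]) & sp$neighbour_id_a != sp$neighbour_id_b
    if (!any(miss)) return(NULL)
    data.frame(a = pmin(sp$neighbour_id_a[miss], sp$neighbour_id_b[miss]),
               b = pmax(sp$neighbour_id_a[miss], sp$neighbour_id_b[miss]),
               stringsAsFactors = FALSE)
  }), list(data.frame(a = character(), b = character(), stringsAsFactors = FALSE)))))
  if (nrow(need) && !is.null(db) && !is.null(params)) {
    lut <- new.env(parent = emptyenv())
    for (bb in unique(need$b)) {
      aa <- need$a[need$b == bb]
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(db$seqs[aa]), Biostrings::AAString(db$seqs[[bb]]),
        type = "local", substitutionMatrix = params$substitution_matrix,
        gapOpening = params$gap_open, gapExtension = params$gap_extend,
        scoreOnly = TRUE)
      e <- evalue_from_score(al, nchar(db$seqs[aa]), nchar(db$seqs[[bb]]), params)
      for (t in seq_along(aa))
        assign(paste(aa[t], bb, sep = "\r"), e[t], envir = lut)
    }
    evs <- lapply(seq_along(shared), function(pp) {
      sp <- shared[[pp]]
      if (!nrow(sp)) return(numeric(0))
      ev <- evs[[pp]]
      for (r in which(is.na(ev))) {
        key <- paste(pmin(sp$neighbour_id_a[r], sp$neighbour_id_b[r]),
                     pmax(sp$neighbour_id_a[r], sp$neighbour_id_b[r]), sep = "\r")
        ev[r] <- get0(key, envir = lut, ifnotfound = NA_real_)
      }
      ev
    })
  }

  ea <- integer(); eb <- integer()
  rows <- list()
  for (pp in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1L, pp]; j <- pair_idx[2L, pp]
    edge <- score_edge(shared[[pp]], cluster_sizes, strong_cutoff, evs[[pp]])
    rows[[pp]] <- data.frame(
      query_a = queries[i], query_b = queries[j],
      n_shared = nrow(shared[[pp]]), strength = edge$strength,
      strong = edge$strong, stringsAsFactors = FALSE)
    if (edge$strong) { ea <- c(ea, i); eb <- c(eb, j) }
  }
  edges <- do.call(rbind, c(rows, list(data.frame(
    query_a = character(), query_b = character(), n_shared = integer(),
    strength = numeric(), strong = logical(), stringsAsFactors = FALSE))))

  comp <- components_idx(nq, ea, eb)
  sublineage <- sprintf("L%d", comp)
  i <- match(queries, db$orf_table$orf_id)
  role <- if (!is.null(roles)) unname(roles$role[match(queries, roles$orf_id)])
          else rep(NA_character_, nq)
  nodes <- data.frame(orf_id = queries,
                      wgd_status = db$orf_table$wgd_status[i],
                      role = role, sublineage = sublineage,
                      stringsAsFactors = FALSE)
  maj <- vapply(split(nodes$role, nodes$sublineage), function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) NA_character_ else names(sort(table(r), decreasing = TRUE))[1L]
  }, "")
  sub_roles <- data.frame(sublineage = names(maj), majority_role = unname(maj),
                          n = as.integer(table(nodes$sublineage)[names(maj)]),
                          stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, sublineage_roles = sub_roles),
            class = "lineage_graph")
}

#' @export
print.lineage_graph <- function(x, ...) {
  cat("Synteny lineage graph:", nrow(x$nodes), "query genes,",
      sum(x$edges$strong), "strong /", nrow(x$edges), "edges,",
      nrow(x$sublineage_roles), "sub-lineages\n")
  for (i in seq_len(nrow(x$sublineage_roles)))
    cat(sprintf("  %s: n=%d, majority role %s\n",
                x$sublineage_roles$sublineage[i], x$sublineage_roles$n[i],
                x$sublineage_roles$majority_role[i]))
  invisible(x)
}

#' Write synteny edge and sub-lineage partition tables
#'
#' @param lg a `lineage_graph`.
#' @param edges_path,partition_path output TSV paths.
#' @export
write_lineage_tables <- function(lg, edges_path, partition_path) {
  write_tsv(lg$edges, edges_path)
  write_tsv(lg$nodes, partition_path)
  invisible(c(edges_path, partition_path))
}
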