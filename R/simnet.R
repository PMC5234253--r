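#' Build an undirected protein-similarity network
#'
#' Nodes are ORF ids; an undirected edge joins two ORFs whenever at least one
#' directed hit exists for the pair, weighted by the minimum e-value over the
#' two directions. Self-hits are discarded; isolated nodes are retained.
#'
#' @param hits a `pairwise_hits` data.frame (see [all_vs_all()] or
#'   [read_hit_table()]).
#' @param node_universe character vector of all node ids (e.g.
#'   `db$orf_table$orf_id`); every hit id must belong to it.
#' @return an object of class `similarity_network` with fields `nodes` and
#'   `edges` (data.frame `node_a`, `node_b`, `evalue`; `node_a < node_b`).
#' @export
build_network <- function(hits, node_universe) {
  node_universe <- unique(as.character(node_universe))
  bad <- setdiff(unique(c(hits$query_id, hits$subject_id)), node_universe)
  if (length(bad)) stop2("hit references unknown node: ", bad[1L])
  keep <- hits$query_id != hits$subject_id
  a <- pmin(hits$query_id[keep], hits$subject_id[keep])
  b <- pmax(hits$query_id[keep], hits$subject_id[keep])
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    ev <- tapply(hits$evalue[keep], key, min)
    ab <- do.call(rbind, strsplit(names(ev), "\r", fixed = TRUE))
    edges <- data.frame(node_a = ab[, 1L], node_b = ab[, 2L],
                        evalue = as.numeric(ev), stringsAsFactors = FALSE)
    edges <- edges[order(edges$node_a, edges$node_b), ]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_a = character(), node_b = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = node_universe, edges = edges),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat("Protein similarity network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

net_indices <- function(net) {
  list(ea = match(net$edges$node_a, net$nodes),
       eb = match(net$edges$node_b, net$nodes))
}

check_exponent <- function(exponent, lo = -60L, hi = -1L) {
  exponent <- assert_count(-exponent, "negated exponent", min = 1L) * -1L
  if (exponent < lo || exponent > hi)
    stop2("exponent must lie in ", lo, "..", hi)
  exponent
}

#' Retrieve a gene family by breadth-first network traversal
#'
#' Members are all ORFs reachable from the seed through edges whose e-value is
#' at most `10^exponent` -- i.e. the connected component of the seed in the
#' thresholded similarity network, found by breadth-first traversal.
#'
#' @param net a `similarity_network`.
#' @param seed_id seed ORF id (the starting node; always a member).
#' @param exponent integer e-value exponent in -60..-1.
#' @return an object of class `family_cluster` with fields `seed_id`,
#'   `exponent_cut` and `member_ids` (sorted character vector).
#' @export
retrieve_cluster <- function(net, seed_id, exponent) {
  exponent <- check_exponent(exponent)
  seed <- match(seed_id, net$nodes)
  if (is.na(seed)) stop2("unknown seed node: ", seed_id)
  keep <- net$edges$evalue <= 10^exponent
  idx <- net_indices(net)
  comp <- bfs_component_idx(length(net$nodes), idx$ea[keep], idx$eb[keep], seed)
  structure(list(seed_id = seed_id, exponent_cut = exponent,
                 member_ids = sort(net$nodes[comp])),
            class = "family_cluster")
}

#' @export
print.family_cluster <- function(x, ...) {
  cat(sprintf("Family cluster: seed %s, e-value cut 1e%d, %d members\n",
              x$seed_id, x$exponent_cut, length(x$member_ids)))
  invisible(x)
}

#' Sweep e-value thresholds and record the retrieval curve
#'
#' Runs [retrieve_cluster()] at every integer exponent in `lo..hi` and records
#' the retrieved-set size. The curve is non-decreasing in the exponent since
#' relaxing the threshold only adds edges.
#'
#' @param net a `similarity_network`.
#' @param seed_id seed ORF id.
#' @param lo,hi integer exponent range (defaults -60..-1).
#' @return an object of class `retrieval_curve` with fields `seed_id`,
#'   `exponents` and `counts`.
#' @export
sweep_thresholds <- function(net, seed_id, lo = -60L, hi = -1L) {
  lo <- check_exponent(lo, lo = -1000L); hi <- check_exponent(hi, lo = -1000L)
  if (lo > hi) stop2("lo must be <= hi")
  seed <- match(seed_id, net$nodes)
  if (is.na(seed)) stop2("unknown seed node: ", seed_id)
  idx <- net_indices(net)
  exps <- lo:hi
  counts <- vapply(exps, function(e) {
    keep <- net$edges$evalue <= 10^e
    length(bfs_component_idx(length(net$nodes), idx$ea[keep], idx$eb[keep], seed))
  }, 1L)
  structure(list(seed_id = seed_id, exponents = exps, counts = counts),
            class = "retrieval_curve")
}

#' @export
print.retrieval_curve <- function(x, ...) {
  cat(sprintf("Retrieval curve for seed %s over exponents %d..%d (counts %d..%d)\n",
              x$seed_id, min(x$exponents), max(x$exponents),
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Plot a retrieval curve
#'
#' @param x a `retrieval_curve`.
#' @param ... passed to [plot()].
#' @method plot retrieval_curve
#' @export
plot.retrieval_curve <- function(x, ...) {
  plot(x$exponents, x$counts, type = "s", xlab = "e-value exponent",
       ylab = "sequences retrieved",
       main = paste("Seed", x$seed_id), ...)
  invisible(x)
}

#' Detect clustering plateaus in a retrieval curve
#'
#' Splits the exponent sweep into maximal runs of consecutive exponents whose
#' counts differ from the run's first count by at most `tolerance`. The
#' segments tile the sweep range without overlap.
#'
#' @param curve a `retrieval_curve`.
#' @param tolerance non-negative integer count tolerance (default 0: strictly
#'   constant runs).
#' @return data.frame with columns `exponent_lo`, `exponent_hi`, `count` (the
#'   run's first count).
#' @export
detect_plateaus <- function(curve, tolerance = 0L) {
  tolerance <- assert_count(tolerance, "tolerance")
  exps <- curve$exponents; counts <- curve$counts
  lo <- integer(); hi <- integer(); cnt <- integer()
  start <- 1L
  for (i in seq_along(exps)) {
    if (abs(counts[i] - counts[start]) > tolerance) {
      lo <- c(lo, exps[start]); hi <- c(hi, exps[i - 1L]); cnt <- c(cnt, counts[start])
      start <- i
    }
  }
  lo <- c(lo, exps[start]); hi <- c(hi, exps[length(exps)]); cnt <- c(cnt, counts[start])
  data.frame(exponent_lo = lo, exponent_hi = hi, count = cnt)
}

#' Suggest an e-value cut from the plateau structure
#'
#' Returns the most permissive exponent of the widest plateau that still
#' excludes the next merge (i.e. the widest plateau that is followed by a
#' plateau of larger count); with a single plateau its upper exponent is
#' returned. Ties are broken toward the more stringent plateau. This is a
#' suggestion to be reviewed, mirroring an expert-chosen cut, never a silent
#' truth.
#'
#' @param plateaus data.frame from [detect_plateaus()].
#' @return integer exponent.
#' @export
auto_plateau_cut <- function(plateaus) {
  if (nrow(plateaus) == 0L) stop2("no plateaus")
  cand <- if (nrow(plateaus) > 1L) plateaus[-nrow(plateaus), ] else plateaus
  width <- cand$exponent_hi - cand$exponent_lo + 1L
  pick <- which(width == max(width))[1L]
  as.integer(cand$exponent_hi[pick])
}

#' Partition all network nodes into similarity clusters at a cut
#'
#' Connected components of the thresholded network; labels (`c0001`, ...) are
#' assigned in order of first node appearance, so the partition is
#' deterministic.
#'
#' @param net a `similarity_network`.
#' @param exponent integer e-value exponent.
#' @return named character vector mapping every node id to its cluster label.
#' @export
cluster_all <- function(net, exponent) {
  exponent <- check_exponent(exponent)
  keep <- net$edges$evalue <= 10^exponent
  idx <- net_indices(net)
  comp <- components_idx(length(net$nodes), idx$ea[keep], idx$eb[keep])
  stats::setNames(sprintf("c%04d", comp), net$nodes)
}

#' Write network edges as TSV
#'
#' @param net a `similarity_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  write_tsv(net$edges, path)
}

#' Write a network in GraphML format
#'
#' @param net a `similarity_network`.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="evalue" for="edge" attr.name="evalue" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"/>', net$nodes), con)
  if (nrow(net$edges))
    writeLines(sprintf('    <edge source="%s" target="%s"><data key="evalue">%.6g</data></edge>',
                       net$edges$node_a, net$edges$node_b, net$edges$evalue), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}

#' Write cluster membership TSV
#'
#' @param cluster a `family_cluster`.
#' @param path output path.
#' @export
write_cluster_members <- function(cluster, path) {
  write_tsv(data.frame(orf_id = cluster$member_ids,
                       cluster_seed = cluster$seed_id,
                       exponent = cluster$exponent_cut), path)
}
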