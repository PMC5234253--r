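`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop2(what, " must be a non-empty character scalar")
  x
}

assert_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min)
    stop2(what, " must be an integer >= ", min)
  as.integer(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "", check.names = FALSE)
}

# Adjacency list for an undirected edge list over nodes 1..n.
build_adjacency <- function(n_nodes, ea, eb) {
  adj <- vector("list", n_nodes)
  if (length(ea)) {
    sp <- split(c(eb, ea), c(ea, eb))
    adj[as.integer(names(sp))] <- sp
  }
  adj
}

# Breadth-first traversal from seed over a prebuilt adjacency list.
# Returns sorted integer indices of the connected component containing seed.
bfs_from <- function(adj, seed, visited = logical(length(adj))) {
  visited[seed] <- TRUE
  queue <- seed
  head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]
    head <- head + 1L
    nb <- adj[[v]]
    if (!is.null(nb)) {
      new <- nb[!visited[nb]]
      if (length(new)) {
        visited[new] <- TRUE
        queue <- c(queue, new)
      }
    }
  }
  sort(which(visited))
}

bfs_component_idx <- function(n_nodes, ea, eb, seed) {
  bfs_from(build_adjacency(n_nodes, ea, eb), seed)
}

# All connected components; integer membership vector, labels numbered in
# order of first appearance along the node vector.
components_idx <- function(n_nodes, ea, eb) {
  adj <- build_adjacency(n_nodes, ea, eb)
  comp <- integer(n_nodes)
  label <- 0L
  for (v in seq_len(n_nodes)) {
    if (comp[v] == 0L) {
      label <- label + 1L
      comp[bfs_from(adj, v)] <- label
    }
  }
  comp
}
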