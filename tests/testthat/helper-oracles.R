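# Independent oracles used across the suite. These deliberately re-derive
# results through different algorithms/code paths than the package.

# Brute-force affine-gap DP (three-state recurrences written out in R).
# Gap of length L costs open + L * ext, matching the package's convention.
oracle_align <- function(a, b, mat, open, ext, type = c("local", "global")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column: residue vs residue
  X <- matrix(NEG, n + 1, m + 1)  # last column: residue of a vs gap
  Y <- matrix(NEG, n + 1, m + 1)  # last column: gap vs residue of b
  if (type == "global") {
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  } else {
    M[, ] <- NEG; M[1, ] <- 0; M[, 1] <- 0  # free restart anywhere
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      diag_best <- max(M[i, j], X[i, j], Y[i, j])
      if (type == "local") diag_best <- max(diag_best, 0)
      M[i + 1, j + 1] <- mat[av[i], bv[j]] + diag_best
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
      if (type == "local") best_local <- max(best_local, M[i + 1, j + 1])
    }
  }
  if (type == "local") best_local
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_peptide <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), len, TRUE),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
}

# Exhaustive motif-scan oracle: tries every offset, run-length combination
# and strand independently of the package's scanner.
oracle_scan <- function(seq, motif, both_strands = TRUE) {
  hits <- list()
  scan_chars <- function(chars, strand, n) {
    reps <- lapply(motif$elements, function(e) e$min:e$max)
    grid <- expand.grid(reps, KEEP.OUT.ATTRS = FALSE)
    for (g in seq_len(nrow(grid))) {
      sets <- list()
      for (k in seq_along(motif$elements))
        sets <- c(sets, rep(list(motif$elements[[k]]$bases), grid[g, k]))
      L <- length(sets)
      if (L > length(chars)) next
      for (st in 1:(length(chars) - L + 1)) {
        ok <- TRUE
        for (p in seq_len(L)) {
          if (!chars[st + p - 1] %in% sets[[p]]) { ok <- FALSE; break }
        }
        if (ok) {
          if (strand == "+") {
            hits[[length(hits) + 1]] <<- c(st - 1, st - 1 + L, "+")
          } else {
            hits[[length(hits) + 1]] <<- c(n - (st - 1 + L), n - (st - 1), "-")
          }
        }
      }
    }
  }
  fwd <- strsplit(toupper(seq), "")[[1]]
  n <- length(fwd)
  scan_chars(fwd, "+", n)
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    scan_chars(rev(unname(comp[fwd])), "-", n)
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer(),
                                       strand = character()))
  d <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  names(d) <- c("start", "end", "strand")
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d[order(d$start, d$end, d$strand), ]
}

# Connected component of seed via igraph (independent of the package BFS).
oracle_component <- function(net, seed_id, exponent) {
  keep <- net$edges$evalue <= 10^exponent
  g <- igraph::graph_from_data_frame(
    net$edges[keep, c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = net$nodes))
  comp <- igraph::components(g)
  sort(net$nodes[comp$membership == comp$membership[match(seed_id, net$nodes)]])
}

# Random similarity network over n nodes.
random_network <- function(n, p_edge = 0.03) {
  nodes <- sprintf("n%03d", seq_len(n))
  cmb <- utils::combn(n, 2)
  pick <- runif(ncol(cmb)) < p_edge
  hits <- data.frame(query_id = nodes[cmb[1, pick]],
                     subject_id = nodes[cmb[2, pick]],
                     evalue = 10^runif(sum(pick), -60, 0),
                     stringsAsFactors = FALSE)
  build_network(hits, nodes)
}
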