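chain_network <- function() {
  hits <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                     evalue = c(1e-20, 1e-5), stringsAsFactors = FALSE)
  build_network(hits, c("a", "b", "c"))
}

test_that("build_network collapses directed hits by the minimum e-value", {
  hits <- data.frame(query_id = c("a", "b", "a"),
                     subject_id = c("b", "a", "a"),
                     evalue = c(1e-20, 1e-18, 1e-50), stringsAsFactors = FALSE)
  net <- build_network(hits, c("a", "b", "c", "d", "e"))
  expect_identical(nrow(net$edges), 1L)         # self-hit dropped, pair merged
  expect_equal(net$edges$evalue, 1e-20)
  expect_identical(length(net$nodes), 5L)       # isolated nodes retained
  none <- build_network(hits[0, ], c("a", "b", "c", "d", "e"))
  expect_identical(nrow(none$edges), 0L)
  expect_error(build_network(hits, "a"), "unknown node")
})

test_that("retrieve_cluster walks the thresholded component", {
  net <- chain_network()
  expect_identical(retrieve_cluster(net, "a", -10)$member_ids, c("a", "b"))
  expect_identical(retrieve_cluster(net, "a", -3)$member_ids, c("a", "b", "c"))
  expect_identical(retrieve_cluster(net, "c", -10)$member_ids, "c")
  expect_error(retrieve_cluster(net, "zz", -10), "unknown seed")
})

test_that("sweep counts the chain example and stays at 1 on edgeless networks", {
  net <- chain_network()
  curve <- sweep_thresholds(net, "a")
  expect_identical(curve$counts[curve$exponents <= -21], rep(1L, 40))
  expect_identical(curve$counts[curve$exponents >= -20 & curve$exponents <= -6],
                   rep(2L, 15))
  expect_identical(curve$counts[curve$exponents >= -5], rep(3L, 5))
  lonely <- build_network(data.frame(query_id = character(),
                                     subject_id = character(),
                                     evalue = numeric()), c("a", "b"))
  expect_true(all(sweep_thresholds(lonely, "a")$counts == 1L))
})

test_that("plateau detection tiles the sweep range", {
  net <- chain_network()
  curve <- sweep_thresholds(net, "a")
  pl <- detect_plateaus(curve)
  expect_identical(nrow(pl), 3L)
  expect_identical(pl$count, c(1L, 2L, 3L))
  expect_identical(sum(pl$exponent_hi - pl$exponent_lo + 1L), 60L)
  expect_identical(pl$exponent_lo[-1L], pl$exponent_hi[-nrow(pl)] + 1L)
  # constant curve: a single plateau covering everything
  flat <- structure(list(seed_id = "a", exponents = -60:-1,
                         counts = rep(4L, 60)), class = "retrieval_curve")
  expect_identical(nrow(detect_plateaus(flat)), 1L)
  # tolerance merges nearby counts
  wob <- structure(list(seed_id = "a", exponents = -10:-1,
                        counts = c(5L, 6L, 5L, 5L, 6L, 9L, 9L, 9L, 9L, 9L)),
                   class = "retrieval_curve")
  expect_identical(nrow(detect_plateaus(wob, tolerance = 1L)), 2L)
})

test_that("auto cut picks the widest pre-merge plateau's permissive end", {
  net <- chain_network()
  pl <- detect_plateaus(sweep_thresholds(net, "a"))
  expect_identical(auto_plateau_cut(pl), -21L)
  one <- data.frame(exponent_lo = -60L, exponent_hi = -1L, count = 7L)
  expect_identical(auto_plateau_cut(one), -1L)
})

test_that("cluster_all partitions every node deterministically", {
  net <- chain_network()
  cl <- cluster_all(net, -10)
  expect_identical(length(cl), 3L)
  expect_identical(unname(cl["a"]), unname(cl["b"]))
  expect_false(cl[["a"]] == cl[["c"]])
  cl2 <- cluster_all(net, -3)
  expect_identical(length(unique(cl2)), 1L)
})

test_that("network exports are written", {
  net <- chain_network()
  p1 <- tempfile(fileext = ".tsv"); p2 <- tempfile(fileext = ".graphml")
  write_network(net, p1); write_network_graphml(net, p2)
  expect_identical(nrow(read.table(p1, header = TRUE)), 2L)
  expect_true(any(grepl("graphml", readLines(p2))))
})

test_that("traversal equals the independent component oracle on random graphs", {
  set.seed(21)
  for (rep in 1:25) {
    net <- random_network(sample(20:80, 1))
    seed <- sample(net$nodes, 1)
    e <- sample(-60:-1, 1)
    expect_identical(retrieve_cluster(net, seed, e)$member_ids,
                     oracle_component(net, seed, e))
  }
})

test_that("member sets nest as the threshold relaxes", {
  set.seed(22)
  for (rep in 1:10) {
    net <- random_network(60)
    seed <- sample(net$nodes, 1)
    prev <- character()
    for (e in seq(-60, -1, by = 5)) {
      cur <- retrieve_cluster(net, seed, e)$member_ids
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})
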