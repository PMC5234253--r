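mk_window <- function(offsets, labels, ids = NULL, query = "q") {
  ids <- ids %||% paste0("n", seq_along(offsets))
  label_window(data.frame(orf_id = ids, offset = offsets,
                          stringsAsFactors = FALSE),
               stats::setNames(labels, ids), query)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("window labelling falls back to singleton labels", {
  w <- label_window(data.frame(orf_id = c("x", "y", "z"), offset = c(-1L, 1L, 2L)),
                    c(x = "f7", z = "f7"))
  expect_identical(w$family_label[w$orf_id == "x"], "f7")
  expect_identical(w$family_label[w$orf_id == "z"], "f7")
  expect_match(w$family_label[w$orf_id == "y"], "^singleton:")
})

test_that("shared pairs match labels, prefer closest instances, skip singletons", {
  wa <- mk_window(c(3L, 9L), c("f2", "f2"), c("a1", "a2"))
  wb <- mk_window(-1L, "f2", "b1")
  sp <- shared_pairs(wa, wb)
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$offset_a, 3L)        # closest of +3 / +9
  expect_identical(sp$offset_b, -1L)
  # tie on |offset| resolved toward the upstream (negative) instance
  wt <- mk_window(c(-2L, 2L), c("f5", "f5"), c("t1", "t2"))
  sp2 <- shared_pairs(wt, mk_window(1L, "f5", "u1"))
  expect_identical(sp2$offset_a, -2L)
  # symmetry up to swapping the offset columns
  sp3 <- shared_pairs(wb, wa)
  expect_identical(sp3$offset_a, sp$offset_b)
  expect_identical(sp3$offset_b, sp$offset_a)
  # disjoint label sets and singleton labels never match
  expect_identical(nrow(shared_pairs(mk_window(1L, "f1", "p1"),
                                     mk_window(1L, "f9", "p2"))), 0L)
  ws1 <- label_window(data.frame(orf_id = "s1", offset = 1L), c())
  ws2 <- label_window(data.frame(orf_id = "s2", offset = 1L), c())
  expect_identical(nrow(shared_pairs(ws1, ws2)), 0L)
})

test_that("edge strength follows the closeness x similarity x rarity product", {
  none <- score_edge(shared_pairs(mk_window(1L, "f1", "x"),
                                  mk_window(1L, "f2", "y")),
                     c(f1 = 2L, f2 = 2L))
  expect_identical(none$strength, 0)
  expect_false(none$strong)
  pairs <- data.frame(family_label = "f1", offset_a = 1L, offset_b = -1L,
                      neighbour_id_a = "na", neighbour_id_b = "nb",
                      stringsAsFactors = FALSE)
  one <- score_edge(pairs, c(f1 = 2L), pair_evalues = 1e-60)
  expect_equal(one$strength, 1)            # 1 * 1 * 1
  # each factor scales as documented
  expect_equal(score_edge(pairs, c(f1 = 4L), pair_evalues = 1e-60)$strength, 0.5)
  expect_equal(score_edge(pairs, c(f1 = 2L), pair_evalues = 1e-30)$strength, 0.5)
  far <- pairs; far$offset_a <- 5L
  expect_equal(score_edge(far, c(f1 = 2L), pair_evalues = 1e-60)$strength, 0.2)
  # absent e-value scores full similarity
  expect_equal(score_edge(pairs, c(f1 = 2L))$strength, 1)
  # adding a pair never decreases strength
  two <- rbind(pairs, data.frame(family_label = "f2", offset_a = 7L,
                                 offset_b = 7L, neighbour_id_a = "nc",
                                 neighbour_id_b = "nd"))
  expect_gte(score_edge(two, c(f1 = 2L, f2 = 3L))$strength,
             score_edge(pairs, c(f1 = 2L))$strength)
  # strength bounded by one unit per shared label
  expect_lte(score_edge(two, c(f1 = 2L, f2 = 2L))$strength, 2)
  expect_error(score_edge(pairs, c(f1 = 1L)), "cluster size")
})

test_that("strength is invariant to window entry order", {
  set.seed(31)
  labs <- c("f1", "f2", "f3", "f4")
  wa <- mk_window(c(-3L, -1L, 2L, 5L), labs, paste0("a", 1:4))
  wb <- mk_window(c(-2L, 1L, 3L, 9L), labs, paste0("b", 1:4))
  sizes <- c(f1 = 3L, f2 = 5L, f3 = 2L, f4 = 8L)
  base <- score_edge(shared_pairs(wa, wb), sizes)$strength
  perm <- sample(nrow(wa))
  wa2 <- label_window(data.frame(orf_id = wa$orf_id[perm],
                                 offset = wa$offset[perm]),
                      stats::setNames(wa$family_label, wa$orf_id))
  expect_equal(score_edge(shared_pairs(wa2, wb), sizes)$strength, base)
})

test_that("lineage graph separates sub-lineages on a small simulation", {
  sim <- simulate_genomes(small_sim_config())
  db <- sim$db
  hits <- all_vs_all(db, alignment_params(), filter_word = 5)
  net <- build_network(hits, db$orf_table$orf_id)
  queries <- sort(names(sim$truth$sublineage))
  clustering <- cluster_all(net, -6)
  roles <- assign_roles(queries, db)
  lg <- build_lineage_graph(db, queries, clustering, net = net, roles = roles)
  # partition agrees with the simulated sub-lineage truth
  truth <- sim$truth$sublineage[lg$nodes$orf_id]
  tab <- table(lg$nodes$sublineage, truth)
  expect_true(all(rowSums(tab > 0) == 1))   # no block mixes truth labels
  expect_true(all(colSums(tab > 0) == 1))   # no truth label splits
  # strong edges only within blocks (partition blocks connected by construction)
  strong <- lg$edges[lg$edges$strong, ]
  sl <- stats::setNames(lg$nodes$sublineage, lg$nodes$orf_id)
  expect_true(all(sl[strong$query_a] == sl[strong$query_b]))
})

test_that("queries without shared neighbours form singleton sub-lineages", {
  fx <- write_fixture_genome(ids = sprintf("g%d", 1:6),
                             seqs = replicate(6, random_peptide(40)),
                             scaffolds = c("s1", "s1", "s1", "s2", "s2", "s2"))
  db <- compile_db(list(load_genome(fx$fasta, fx$order, "lone", 1, "pre")))
  clustering <- stats::setNames(sprintf("c%d", 1:6), db$orf_table$orf_id)
  lg <- build_lineage_graph(db, c("lone_1_g2", "lone_1_g5"), clustering,
                            params = alignment_params())
  expect_identical(nrow(lg$sublineage_roles), 2L)
  expect_true(all(!lg$edges$strong))
})
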