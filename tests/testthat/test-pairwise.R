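params <- alignment_params()

test_that("local alignment scores identity runs and is symmetric", {
  r <- align_local("AAAA", "AAAA", params)
  expect_equal(r$score, 16)            # 4 x BLOSUM62 S(A,A) = 4
  expect_equal(r$identity_pct, 100)
  set.seed(11)
  for (i in 1:10) {
    a <- random_peptide(sample(4:10, 1)); b <- random_peptide(sample(4:10, 1))
    expect_equal(align_local(a, b, params)$score,
                 align_local(b, a, params)$score)
  }
  expect_error(align_local("", "MKV", params), "non-empty")
})

test_that("global alignment reproduces the hand-computed toy example", {
  toy <- list(match = 1, mismatch = -1, gap_open = 0, gap_extend = 2)
  r <- align_global("ACDE", "ACE", toy)
  expect_equal(r$identity_pct, 75)     # ACDE / AC-E
  expect_equal(r$gap_pct, 25)
  expect_equal(r$aln_length, 4L)
  s <- align_global("MKVLA", "MKVLA", params)
  expect_equal(s$identity_pct, 100)
  expect_equal(s$gap_pct, 0)
})

test_that("global stats are swap-invariant and column percentages sum to 100", {
  set.seed(12)
  for (i in 1:10) {
    a <- random_peptide(sample(5:15, 1)); b <- random_peptide(sample(5:15, 1))
    ra <- align_global(a, b, params); rb <- align_global(b, a, params)
    expect_equal(ra$identity_pct, rb$identity_pct)
    expect_equal(ra$gap_pct, rb$gap_pct)
    expect_equal(ra$identity_pct + ra$mismatch_pct + ra$gap_pct, 100)
    expect_true(ra$identity_pct >= 0 && ra$identity_pct <= 100)
    expect_true(ra$gap_pct >= 0 && ra$gap_pct <= 100)
  }
})

test_that("e-value stand-in matches the closed form and its limits", {
  expect_equal(evalue_from_score(0, 20, 30, params), 0.041 * 20 * 30)
  expect_error(evalue_from_score(10, 0, 5, params), ">= 1")
  expect_error(alignment_params(ka_lambda = -1), "positive")
})

test_that("all-vs-all reports all ordered pairs of identical ORFs", {
  fx <- write_fixture_genome(ids = c("x1", "x2", "x3"),
                             seqs = rep("MKVLAEGHWKLMNPQRSTVY", 3))
  db <- compile_db(list(load_genome(fx$fasta, fx$order, "trip", 1, "pre")))
  hits <- all_vs_all(db, params, filter_word = NULL)
  expect_identical(nrow(hits), 6L)
  expect_true(all(hits$identity_pct == 100))
  expect_true(all(hits$query_id != hits$subject_id))
  # single-ORF database: no self-hits
  fx1 <- write_fixture_genome(ids = "only", seqs = "MKVLAEGHWKLMNPQRSTVY")
  db1 <- compile_db(list(load_genome(fx1$fasta, fx1$order, "solo", 1, "pre")))
  expect_identical(nrow(all_vs_all(db1, params, filter_word = NULL)), 0L)
  # word prefilter changes which pairs are attempted, not determinism
  h2 <- all_vs_all(db, params, filter_word = 5)
  expect_identical(h2, all_vs_all(db, params, filter_word = 5))
})

test_that("group identity summary averages cross pairs", {
  fx <- write_fixture_genome(ids = c("a1", "a2", "b1", "b2"),
                             seqs = c("MKVLAEGH", "MKVLAEGH",
                                      "MKVLAEGH", "MELKVWYP"))
  db <- compile_db(list(load_genome(fx$fasta, fx$order, "grps", 1, "pre")))
  one <- group_identity_summary("grps_1_a1", "grps_1_b1", db, params)
  expect_equal(one$mean_identity_pct, 100)
  expect_equal(one$mean_gap_pct, 0)
  expect_identical(one$n_pairs, 1L)
  # 2x2 groups: mean of the four pairwise values computed directly
  ga <- c("grps_1_a1", "grps_1_a2"); gb <- c("grps_1_b1", "grps_1_b2")
  res <- group_identity_summary(ga, gb, db, params)
  vals <- vapply(ga, function(a) vapply(gb, function(b)
    align_global(db$seqs[[a]], db$seqs[[b]], params)$identity_pct, 1), c(1, 1))
  expect_equal(res$mean_identity_pct, mean(vals))
  expect_identical(res$n_pairs, 4L)
  expect_error(group_identity_summary(character(), gb, db, params), "non-empty")
  # within-group: unordered distinct pairs only
  within <- group_identity_summary(ga, ga, db, params)
  expect_identical(within$n_pairs, 1L)
})

test_that("hit tables round-trip through the outfmt-6 dialect", {
  fx <- write_fixture_genome(ids = c("r1", "r2"),
                             seqs = c("MKVLAEGHWKLMNPQRSTVY", "MKVLAEGHWKLMNPQRSTVA"))
  db <- compile_db(list(load_genome(fx$fasta, fx$order, "rtdb", 1, "pre")))
  hits <- all_vs_all(db, params, filter_word = NULL)
  path <- tempfile(fileext = ".tsv")
  write_hit_table(hits, path)
  back <- read_hit_table(path)
  expect_identical(back$query_id, hits$query_id)
  expect_identical(back$subject_id, hits$subject_id)
  expect_equal(back$evalue, hits$evalue, tolerance = 1e-6)
  expect_equal(back$score, hits$score)
})
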