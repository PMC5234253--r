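test_that("load_genome canonicalises ids and renumbers ordinals per scaffold", {
  fx <- write_fixture_genome(ids = c("G1", "G2", "G3"),
                             scaffolds = c("chrA", "chrA", "chrA"))
  g <- load_genome(fx$fasta, fx$order, "sace", 1, "post")
  expect_s3_class(g, "genome_record")
  expect_identical(g$orfs$orf_id, c("sace_1_g1", "sace_1_g2", "sace_1_g3"))
  expect_true(all(startsWith(g$orfs$orf_id, "sace_1_")))
  expect_identical(g$orfs$ordinal, 0:2)
  expect_identical(unname(nchar(g$seqs)), g$orfs$length)
})

test_that("load_genome handles empty input, unplaced ORFs and bad residues", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "empty.faa"); file.create(fa)
  tsv <- file.path(dir, "empty.tsv"); file.create(tsv)
  g <- load_genome(fa, tsv, "zyba", 1, "pre")
  expect_identical(nrow(g$orfs), 0L)

  # one ORF missing from the order table goes to an 'unplaced' scaffold
  fx <- write_fixture_genome(ids = c("A1", "A2", "B9"), order_rows = 1:2)
  g2 <- load_genome(fx$fasta, fx$order, "klla", 2, "pre")
  expect_identical(g2$orfs$scaffold_id[g2$orfs$orf_id == "klla_2_b9"], "unplaced")
  expect_identical(g2$orfs$ordinal[g2$orfs$orf_id == "klla_2_b9"], 0L)

  # stop codons stripped, odd residues mapped to X with a warning
  dir2 <- tempfile(); dir.create(dir2)
  fa2 <- file.path(dir2, "p.faa")
  writeLines(c(">w1", "MKV*", ">w2", "MKBL"), fa2)
  tsv2 <- file.path(dir2, "o.tsv")
  writeLines(c("orf_id\tscaffold_id\trank_hint\tstrand",
               "w1\ts\t1\t+", "w2\ts\t2\t-"), tsv2)
  expect_warning(g3 <- load_genome(fa2, tsv2, "test", 1, "pre"),
                 "non-standard")
  expect_identical(unname(g3$seqs["test_1_w1"]), "MKV")
  expect_identical(unname(g3$seqs["test_1_w2"]), "MKXL")
})

test_that("load_genome rejects duplicate ids and malformed species codes", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "d.faa")
  writeLines(c(">dup", "MKV", ">dup", "MKL"), fa)
  tsv <- file.path(dir, "d.tsv")
  writeLines("orf_id\tscaffold_id\trank_hint\tstrand", tsv)
  expect_error(load_genome(fa, tsv, "sace", 1, "post"), "dup")
  fx <- write_fixture_genome()
  expect_error(load_genome(fx$fasta, fx$order, "toolong", 1, "pre"), "4 letters")
  expect_error(load_genome(fx$fasta, fx$order, "ab", 1, "pre"), "4 letters")
})

test_that("GFF3 gene-order input ranks genes by start coordinate", {
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "p.faa")
  writeLines(c(">ga", "MKVL", ">gb", "MKVA", ">gc", "MELK"), fa)
  gff <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t5000\t6000\t.\t+\t.\tID=gb",
               "chr1\tsrc\tgene\t100\t900\t.\t-\t.\tID=ga",
               "chr1\tsrc\tgene\t9000\t9500\t.\t+\t.\tID=gc"), gff)
  g <- load_genome(fa, gff, "zyro", 1, "pre")
  ord <- g$orfs[order(g$orfs$ordinal), ]
  expect_identical(ord$orf_id, c("zyro_1_ga", "zyro_1_gb", "zyro_1_gc"))
  expect_identical(ord$strand, c("-", "+", "+"))
})

test_that("compile_db sums ORFs and rejects collisions", {
  fx1 <- write_fixture_genome(ids = paste0("a", 1:5), seqs = rep("MKVLA", 5))
  fx2 <- write_fixture_genome(ids = paste0("b", 1:7), seqs = rep("MELKV", 7))
  g1 <- load_genome(fx1$fasta, fx1$order, "spaa", 1, "pre")
  g2 <- load_genome(fx2$fasta, fx2$order, "spab", 1, "post")
  db <- compile_db(list(g1, g2))
  expect_identical(db$total_orf_count, 12L)
  expect_identical(compile_db(list())$total_orf_count, 0L)
  expect_error(compile_db(list(g1, g1)), "duplicate")
})

test_that("genome database round-trips through FASTA + order tables", {
  sim <- simulate_genomes(small_sim_config())
  dir <- tempfile("roundtrip")
  files <- write_genome_db(sim$db, dir)
  recs <- lapply(seq_len(nrow(files)), function(i)
    load_genome(files$fasta[i], files$order[i], files$species_code[i],
                files$strain_index[i], files$wgd_status[i]))
  db2 <- compile_db(recs)
  expect_setequal_chr(db2$orf_table$orf_id, sim$db$orf_table$orf_id)
  o1 <- sim$db$orf_table[order(sim$db$orf_table$orf_id), ]
  o2 <- db2$orf_table[order(db2$orf_table$orf_id), ]
  expect_identical(o2$ordinal, o1$ordinal)
  expect_identical(o2$scaffold_id, o1$scaffold_id)
  expect_identical(db2$seqs[o2$orf_id], sim$db$seqs[o1$orf_id])
})

test_that("neighbourhoods truncate at scaffold ends and never cross scaffolds", {
  n <- 40L
  fx <- write_fixture_genome(ids = sprintf("g%02d", 1:n),
                             seqs = rep("MKVLAE", n),
                             scaffolds = rep("chr1", n))
  db <- compile_db(list(load_genome(fx$fasta, fx$order, "neig", 1, "pre")))
  # interior query: full window
  w <- get_neighbour_ids(db, "neig_1_g21", 15)   # ordinal 20
  expect_identical(w$offset, c(-15:-1, 1:15))
  expect_setequal_chr(w$orf_id, sprintf("neig_1_g%02d", c(6:20, 22:36)))
  # scaffold start: no upstream neighbours
  w0 <- get_neighbour_ids(db, "neig_1_g01", 15)
  expect_true(all(w0$offset > 0))
  # properties: <= 2k entries, strictly increasing offsets, no offset 0
  for (k in c(1, 3, 15)) {
    wk <- get_neighbour_ids(db, "neig_1_g05", k)
    expect_lte(nrow(wk), 2 * k)
    expect_true(all(diff(wk$offset) > 0))
    expect_false(0L %in% wk$offset)
  }
  expect_error(get_neighbour_ids(db, "neig_1_missing", 15), "unknown")

  # single-gene scaffold
  fx1 <- write_fixture_genome(ids = "solo", seqs = "MKWL", scaffolds = "chrS")
  db1 <- compile_db(list(load_genome(fx1$fasta, fx1$order, "solo", 1, "pre")))
  expect_identical(nrow(get_neighbour_ids(db1, "solo_1_solo", 15)), 0L)
})
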