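# In-code fixtures shared across tests.

write_fixture_genome <- function(dir = tempfile("gen"),
                                 ids = c("ORF1", "ORF2", "ORF3"),
                                 seqs = c("MKVLA", "MKVLG", "MKVPA"),
                                 scaffolds = rep("chrA", length(ids)),
                                 strands = rep("+", length(ids)),
                                 order_rows = seq_along(ids)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "prot.faa")
  writeLines(paste0(">", ids, "\n", seqs), fa)
  tsv <- file.path(dir, "order.tsv")
  utils::write.table(
    data.frame(orf_id = ids[order_rows], scaffold_id = scaffolds[order_rows],
               rank_hint = seq_along(order_rows), strand = strands[order_rows]),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  list(fasta = fa, order = tsv, dir = dir)
}

# Tiny 4-leaf simulation used by fast tests.
small_sim_config <- function(seed = 7, ...) {
  tr <- "((prea:0.25,preb:0.25)precl:0.70,(posa:0.25,posb:0.25)postcl:0.80)root;"
  simulation_config(species_tree = tr, n_background_families = 10L,
                    seed = seed, ...)
}

# Reduced 6-leaf simulation for end-to-end determinism checks.
mid_sim_config <- function(seed = 3) {
  tr <- paste0("((prea:0.2,(preb:0.15,prec:0.15):0.05)precl:0.70,",
               "(posa:0.2,(posb:0.15,posc:0.15):0.05)postcl:0.80)root;")
  simulation_config(species_tree = tr, n_background_families = 12L, seed = seed)
}

expect_setequal_chr <- function(a, b) {
  testthat::expect_true(setequal(a, b),
                        label = paste("sets differ:", length(setdiff(a, b)),
                                      "extra,", length(setdiff(b, a)), "missing"))
}
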