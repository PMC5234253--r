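#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config()]) or `genomes` (a list
#' of lists with fields `proteome_fasta`, `gene_order_table`, `species_code`,
#' `strain_index`, `wgd_status`, passed to [load_genome()]) must be supplied.
#'
#' @param simulation optional [simulation_config()].
#' @param genomes optional list of genome input descriptors.
#' @param params an [alignment_params()].
#' @param seed_orf_id ORF id used as the traversal starting node; when `NULL`
#'   and simulating, the track-A query copy of the first post-WGD genome is
#'   used (the analogue of seeding at the S. cerevisiae Haa1 protein).
#' @param exponent_cut integer e-value exponent, or `"auto"` for the plateau
#'   heuristic of [auto_plateau_cut()] (always logged in the summary).
#' @param length_cutoff role-assignment protein length cutoff (aa).
#' @param neighbour_k synteny window half-width in genes (default 15).
#' @param strong_cutoff strong synteny edge threshold.
#' @param filter_word all-vs-all shared-word prefilter length (NULL = exact).
#' @param sweep_range integer `c(lo, hi)` exponent sweep range.
#' @param output_dir directory for all artifacts.
#' @param outgroup optional outgroup ORF id(s).
#' @param seed RNG seed for any pipeline-level randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, genomes = NULL,
                            params = alignment_params(),
                            seed_orf_id = NULL, exponent_cut = "auto",
                            length_cutoff = 450L, neighbour_k = 15L,
                            strong_cutoff = 0.3, filter_word = 5L,
                            sweep_range = c(-60L, -1L),
                            output_dir = tempfile("wgdtrace_run_"),
                            outgroup = NULL, seed = 1L) {
  if (is.null(simulation) == is.null(genomes))
    stop2("provide exactly one of 'simulation' or 'genomes'")
  structure(list(simulation = simulation, genomes = genomes, params = params,
                 seed_orf_id = seed_orf_id, exponent_cut = exponent_cut,
                 length_cutoff = length_cutoff, neighbour_k = neighbour_k,
                 strong_cutoff = strong_cutoff, filter_word = filter_word,
                 sweep_range = sweep_range, output_dir = output_dir,
                 outgroup = outgroup, seed = assert_count(seed, "seed")),
            class = "pipeline_config")
}

config_record <- function(config) {
  p <- config$params
  list(seed = config$seed,
       exponent_cut = config$exponent_cut,
       length_cutoff = config$length_cutoff,
       neighbour_k = config$neighbour_k,
       strong_cutoff = config$strong_cutoff,
       filter_word = config$filter_word,
       sweep_range = config$sweep_range,
       substitution_matrix = attr(p$substitution_matrix, "matrix_name") %||% "custom",
       gap_open = p$gap_open, gap_extend = p$gap_extend,
       ka_lambda = p$ka_lambda, ka_k = p$ka_k,
       report_ceiling = p$report_ceiling,
       simulation = if (!is.null(config$simulation))
         unclass(config$simulation) else NULL)
}

pick_seed_orf <- function(sim) {
  truth <- sim$truth
  cand <- names(truth$sublineage)[truth$sublineage == "HAA1-like"]
  if (!length(cand)) cand <- names(truth$family_membership)[
    truth$family_membership == "famq"]
  sort(cand)[1L]
}

#' Run the full comparative-genomics pipeline
#'
#' Stages: ingest (or simulate) genomes; all-vs-all local alignment; build the
#' similarity network; sweep e-value exponents from the seed and detect
#' plateaus; retrieve the family at the chosen cut and partition the whole
#' proteome set into clusters; assign roles and build a neighbor-joining tree;
#' score gene-neighbourhood synteny and partition the queries into
#' sub-lineages. All artifacts are written under `config$output_dir`; rerun
#' with an identical config and seed is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages (default TRUE).
#' @return invisibly, a list of class `pipeline_result` holding every stage
#'   output plus `summary` and `paths`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  if (!inherits(config, "pipeline_config")) stop2("config must be a pipeline_config")
  say <- function(...) if (!quiet) message(...)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    config = file.path(config$output_dir, "config.json"),
    manifest = file.path(config$output_dir, "manifest.tsv"),
    hits = file.path(config$output_dir, "hits.tsv"),
    network = file.path(config$output_dir, "network_edges.tsv"),
    curve = file.path(config$output_dir, "curve_plateaus.json"),
    members = file.path(config$output_dir, "family_members.tsv"),
    report = file.path(config$output_dir, "cluster_report.tsv"),
    tree = file.path(config$output_dir, "tree.nwk"),
    synteny_edges = file.path(config$output_dir, "synteny_edges.tsv"),
    partition = file.path(config$output_dir, "sublineage_partition.tsv"),
    summary = file.path(config$output_dir, "summary.json"))
  jsonlite::write_json(config_record(config), paths$config,
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  set.seed(config$seed)

  say("stage 1: genome database")
  sim <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_genomes(config$simulation)
    db <- sim$db
    write_truth_tables(sim, file.path(config$output_dir, "truth"))
  } else {
    recs <- lapply(config$genomes, function(g)
      load_genome(g$proteome_fasta, g$gene_order_table, g$species_code,
                  g$strain_index, g$wgd_status))
    db <- compile_db(recs)
  }
  write_db_manifest(db, paths$manifest)

  say("stage 2: all-vs-all alignment (", db$total_orf_count, " ORFs)")
  hits <- all_vs_all(db, config$params, config$filter_word)
  write_hit_table(hits, paths$hits)

  say("stage 3: similarity network")
  net <- build_network(hits, db$orf_table$orf_id)
  write_network(net, paths$network)

  seed_orf <- config$seed_orf_id %||%
    (if (!is.null(sim)) pick_seed_orf(sim) else
      stop2("seed_orf_id is required for real inputs"))
  if (!seed_orf %in% net$nodes) stop2("unknown seed ORF: ", seed_orf)

  say("stage 4: e-value sweep from seed ", seed_orf)
  curve <- sweep_thresholds(net, seed_orf, config$sweep_range[1L],
                            config$sweep_range[2L])
  plateaus <- detect_plateaus(curve)
  cut <- if (identical(config$exponent_cut, "auto")) auto_plateau_cut(plateaus)
         else as.integer(config$exponent_cut)
  jsonlite::write_json(list(seed = seed_orf,
                            exponents = curve$exponents, counts = curve$counts,
                            plateaus = plateaus, chosen_cut = cut,
                            cut_mode = if (identical(config$exponent_cut, "auto"))
                              "auto-plateau" else "fixed"),
                       paths$curve, auto_unbox = TRUE, pretty = TRUE, digits = 10)

  say("stage 5: family retrieval at 1e", cut)
  family <- retrieve_cluster(net, seed_orf, cut)
  clustering <- cluster_all(net, cut)
  write_cluster_members(family, paths$members)

  say("stage 6: role assignment and NJ tree")
  roles <- assign_roles(family$member_ids, db,
                        length_cutoff = config$length_cutoff,
                        outgroup = config$outgroup)
  write_cluster_report(roles, paths$report,
                       cluster_labels = clustering[family$member_ids])
  newick <- if (length(family$member_ids) >= 3L) {
    nw <- nj_tree(pairwise_distances(family$member_ids, db, config$params))
    writeLines(nw, paths$tree)
    nw
  } else NA_character_

  say("stage 7: synteny sub-lineages")
  lineage <- if (length(family$member_ids) >= 2L)
    build_lineage_graph(db, family$member_ids, clustering,
                        k = config$neighbour_k, params = config$params,
                        net = net, strong_cutoff = config$strong_cutoff,
                        roles = roles)
  else NULL
  if (!is.null(lineage))
    write_lineage_tables(lineage, paths$synteny_edges, paths$partition)

  summary <- list(
    n_genomes = length(db$genomes),
    total_orfs = db$total_orf_count,
    n_hits = nrow(hits),
    n_edges = nrow(net$edges),
    seed_orf = seed_orf,
    exponent_cut = cut,
    cut_mode = if (identical(config$exponent_cut, "auto")) "auto-plateau" else "fixed",
    n_plateaus = nrow(plateaus),
    n_members = length(family$member_ids),
    roles = as.list(table(roles$role)),
    n_sublineages = if (!is.null(lineage)) nrow(lineage$sublineage_roles) else 0L,
    n_strong_edges = if (!is.null(lineage)) sum(lineage$edges$strong) else 0L)
  if (!is.null(sim)) {
    truth_fam <- names(sim$truth$family_membership)[
      sim$truth$family_membership == "famq"]
    inter <- intersect(family$member_ids, truth_fam)
    expected_role <- c(`HAA1-like` = "HAA1_orthologue",
                       `CUP2-like` = "CUP2_orthologue",
                       PROTOPLOID = "PROTOPLOID_single")
    truth_roles <- expected_role[sim$truth$sublineage[inter]]
    summary$family_truth_size <- length(truth_fam)
    summary$family_precision <- length(inter) / length(family$member_ids)
    summary$family_recall <- length(inter) / length(truth_fam)
    summary$role_accuracy <- mean(roles$role[match(inter, roles$orf_id)] ==
                                    unname(truth_roles))
    if (!is.null(lineage)) {
      common <- intersect(lineage$nodes$orf_id, names(sim$truth$sublineage))
      summary$sublineage_partition <- as.list(stats::setNames(
        lineage$nodes$sublineage[match(common, lineage$nodes$orf_id)], common))
      summary$sublineage_truth <- as.list(sim$truth$sublineage[common])
    }
  }
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)

  structure(list(db = db, sim = sim, hits = hits, net = net, curve = curve,
                 plateaus = plateaus, cut = cut, family = family,
                 clustering = clustering, roles = roles, newick = newick,
                 lineage = lineage, summary = summary, paths = paths,
                 config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("wgdtrace pipeline run\n")
  cat(sprintf("  genomes: %d   ORFs: %d   stored hits: %d   network edges: %d\n",
              s$n_genomes, s$total_orfs, s$n_hits, s$n_edges))
  cat(sprintf("  seed ORF: %s   cut: 1e%d (%s)   plateaus: %d\n",
              s$seed_orf, s$exponent_cut, s$cut_mode, s$n_plateaus))
  cat(sprintf("  family members: %d   sub-lineages: %d\n",
              s$n_members, s$n_sublineages))
  if (!is.null(s$family_precision))
    cat(sprintf("  vs truth: precision %.3f, recall %.3f, role accuracy %.3f\n",
                s$family_precision, s$family_recall, s$role_accuracy))
  invisible(x)
}
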