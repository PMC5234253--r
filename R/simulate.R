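#' Default 12-leaf species tree with a WGD clade
#'
#' Six protoploid (pre-WGD) leaves and six post-WGD leaves. The whole-genome
#' duplication is placed at the start of the stem branch of the clade labelled
#' `postcl`, so ohnolog copies diverge for the full stem plus the within-clade
#' path, while same-track orthologues diverge only since their speciation.
#' Branch lengths are in expected substitutions per site at `sub_rate = 1`:
#' crown depth 0.25 within either clade (orthologue identity roughly 60--80
#' percent) against long stems (0.70 and 0.80), so cross-clade and
#' cross-duplication paths reach total depth about 2 and neighbour-pair
#' similarity across the WGD is marginal -- the regime in which synteny, not
#' sequence similarity alone, must resolve the sub-lineages.
#'
#' @return Newick text with node labels.
#' @export
default_species_tree <- function() {
  ladder <- function(tips, depth = 0.25, step = 0.04) {
    n <- length(tips)
    inner <- sprintf("(%s:%.2f,%s:%.2f)", tips[n - 1L], depth - (n - 2L) * step,
                     tips[n], depth - (n - 2L) * step)
    for (k in (n - 2L):1L) {
      inner <- sprintf("(%s:%.2f,%s:%.2f)", tips[k], depth - (k - 1L) * step,
                       inner, step)
    }
    inner
  }
  pre <- ladder(c("prea", "preb", "prec", "pred", "pree", "pref"))
  post <- ladder(c("posa", "posb", "posc", "posd", "pose", "posf"))
  sprintf("(%sprecl:0.70,%spostcl:0.80)root;", pre, post)
}

#' Simulation configuration
#'
#' Parameters of the WGD-aware genome-evolution simulator. Defaults emulate
#' the study system: a query transcription-factor family present single-copy
#' in protoploid species and (mostly) two-copy in post-WGD species; a 620-aa
#' ancestral query protein (the protoploid average is ~622 aa) with an
#' absolutely conserved 124-aa N-terminal DNA-binding domain; Cup2-style
#' shrinkage of one post-WGD sub-lineage into the 221--356 aa range; conserved
#' gene order with optional local shuffling; and background gene families of
#' 250--400 aa providing the neighbourhood signal.
#'
#' @param species_tree Newick text with branch lengths and a labelled WGD
#'   clade.
#' @param wgd_node label of the internal node whose stem branch carries the
#'   WGD (every leaf below it is post-WGD).
#' @param n_background_families number of single-copy ancestral background
#'   genes flanking the query gene.
#' @param retention_prob probability that each duplicated copy survives in a
#'   post-WGD genome (at least one copy of each family always survives).
#' @param sub_rate substitutions per site per unit branch length.
#' @param indel_rate per-site indel event probability per unit branch length.
#' @param conserved_prefix_len length (aa) of the absolutely conserved
#'   N-terminal domain of the query protein.
#' @param ancestral_query_len ancestral query protein length (aa).
#' @param truncation_target_range length range (aa) into which the truncated
#'   post-WGD sub-lineage falls.
#' @param background_len_range ancestral background protein length range (aa).
#' @param shuffle_rate expected gene-order rearrangement events per branch
#'   (Poisson).
#' @param seed integer RNG seed; the same seed reproduces the simulation
#'   byte-for-byte.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(species_tree = default_species_tree(),
                              wgd_node = "postcl",
                              n_background_families = 30L,
                              retention_prob = 0.9,
                              sub_rate = 1.0,
                              indel_rate = 0.01,
                              conserved_prefix_len = 124L,
                              ancestral_query_len = 620L,
                              truncation_target_range = c(221L, 356L),
                              background_len_range = c(250L, 400L),
                              shuffle_rate = 0,
                              seed = 1L) {
  if (retention_prob < 0 || retention_prob > 1) stop2("retention_prob must be in [0,1]")
  if (conserved_prefix_len >= ancestral_query_len)
    stop2("conserved_prefix_len must be smaller than the ancestral query length")
  if (sub_rate < 0 || indel_rate < 0 || shuffle_rate < 0)
    stop2("rates must be non-negative")
  structure(list(species_tree = species_tree, wgd_node = wgd_node,
                 n_background_families = assert_count(n_background_families,
                                                      "n_background_families", 1L),
                 retention_prob = retention_prob, sub_rate = sub_rate,
                 indel_rate = indel_rate,
                 conserved_prefix_len = as.integer(conserved_prefix_len),
                 ancestral_query_len = as.integer(ancestral_query_len),
                 truncation_target_range = as.integer(truncation_target_range),
                 background_len_range = as.integer(background_len_range),
                 shuffle_rate = shuffle_rate, seed = assert_count(seed, "seed")),
            class = "simulation_config")
}

random_protein <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

#' Evolve a protein sequence along a branch
#'
#' Substitutions are drawn independently per site with probability
#' `1 - exp(-sub_rate * branch_length)` and replace the residue by a uniform
#' different amino acid; indel events (geometric lengths, mean 2) are drawn
#' with probability `1 - exp(-indel_rate * branch_length)` per site. Neither
#' ever touches the first `conserved_prefix_len` residues.
#'
#' @param seq protein sequence.
#' @param branch_length branch length (non-negative).
#' @param sub_rate,indel_rate per-site rates per unit branch length.
#' @param conserved_prefix_len number of immutable leading residues
#'   (default 0).
#' @return the evolved sequence.
#' @export
evolve_sequence <- function(seq, branch_length, sub_rate, indel_rate = 0,
                            conserved_prefix_len = 0L) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n <= conserved_prefix_len)
    stop2("sequence must be longer than the conserved prefix")
  mutable <- (conserved_prefix_len + 1L):n
  p_sub <- 1 - exp(-sub_rate * branch_length)
  if (p_sub > 0) {
    hit <- mutable[stats::runif(length(mutable)) < p_sub]
    if (length(hit)) {
      shift <- sample.int(19L, length(hit), replace = TRUE)
      cur <- match(chars[hit], AA_STANDARD)
      cur[is.na(cur)] <- 1L  # X and friends re-enter the standard alphabet
      chars[hit] <- AA_STANDARD[(cur - 1L + shift) %% 20L + 1L]
    }
  }
  p_ind <- 1 - exp(-indel_rate * branch_length)
  if (p_ind > 0) {
    sites <- mutable[stats::runif(length(mutable)) < p_ind]
    for (pos in rev(sites)) {   # right to left keeps earlier positions valid
      len <- stats::rgeom(1L, 0.5) + 1L
      if (stats::runif(1L) < 0.5) {
        upto <- min(length(chars), pos + len - 1L)
        if (pos > conserved_prefix_len && length(chars) - (upto - pos + 1L) >= 1L)
          chars <- chars[-(pos:upto)]
      } else {
        ins <- sample(AA_STANDARD, len, replace = TRUE)
        chars <- append(chars, ins, after = pos)
      }
    }
  }
  paste(chars, collapse = "")
}

#' Truncate a protein to a target length range
#'
#' Removes random deletion blocks strictly downstream of the conserved prefix
#' until the length falls inside `target_range`; sequences already at or
#' below the range maximum are returned unchanged.
#'
#' @param seq protein sequence.
#' @param target_range integer `c(min, max)` target length range (aa).
#' @param conserved_prefix_len immutable leading residues (must be shorter
#'   than `target_range[1]`).
#' @return the truncated sequence.
#' @export
apply_truncation <- function(seq, target_range = c(221L, 356L),
                             conserved_prefix_len = 124L) {
  n <- nchar(seq)
  if (target_range[1L] <= conserved_prefix_len)
    stop2("target_range minimum must exceed the conserved prefix length")
  if (target_range[1L] > target_range[2L]) stop2("invalid target_range")
  if (n <= target_range[2L]) return(seq)
  if (target_range[1L] > n) stop2("target_range infeasible for this sequence")
  target_len <- sample(target_range[1L]:min(target_range[2L], n), 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  while (length(chars) > target_len) {
    need <- length(chars) - target_len
    block <- min(need, 10L + stats::rgeom(1L, 0.1))
    start <- sample((conserved_prefix_len + 1L):(length(chars) - block + 1L), 1L)
    if (start <= conserved_prefix_len) next
    chars <- chars[-(start:(start + block - 1L))]
  }
  paste(chars, collapse = "")
}

# random segment inversion or translocation within one scaffold's gene order
shuffle_order <- function(ord) {
  n <- length(ord)
  if (n < 3L) return(ord)
  len <- min(n - 1L, 1L + stats::rgeom(1L, 0.4))
  start <- sample.int(n - len + 1L, 1L)
  seg <- start:(start + len - 1L)
  if (stats::runif(1L) < 0.5) {
    ord[seg] <- rev(ord[seg])
    ord
  } else {
    rest <- ord[-seg]
    at <- sample.int(length(rest) + 1L, 1L) - 1L
    append(rest, ord[seg], after = at)
  }
}

#' Simulate genome evolution across a whole-genome duplication
#'
#' Evolves an ancestral genome (one scaffold: `n_background_families`
#' single-copy background genes with the query gene in the middle) down the
#' species tree. On the stem branch of the WGD clade the gene order is doubled
#' onto paired scaffolds (`...a` = track A, `...b` = track B) and both copies
#' evolve independently thereafter; in each post-WGD leaf every duplicated
#' copy is retained with `retention_prob` (at least one copy per family always
#' survives) and the track-B query copy is truncated into
#' `truncation_target_range`, emulating the Cup2-style size reduction.
#' Substitutions never touch the conserved N-terminal prefix of the query.
#'
#' @param config a [simulation_config()].
#' @return list of class `wgd_simulation` with elements `db` (a `genome_db`),
#'   `truth` (ground-truth tables: `family_membership`, `ohnolog_pairs`,
#'   `sublineage`, `ancestral_order`) and `config`.
#' @export
simulate_genomes <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config")) stop2("config must be a simulation_config")
  set.seed(config$seed)
  tree <- tryCatch(ape::read.tree(text = config$species_tree),
                   error = function(e) NULL)
  if (is.null(tree)) stop2("malformed species tree")
  ntip <- length(tree$tip.label)
  wgd_node <- which(tree$node.label == config$wgd_node) + ntip
  if (length(wgd_node) != 1L || is.na(wgd_node))
    stop2("wgd_node '", config$wgd_node, "' not found among node labels")

  nb <- config$n_background_families
  fam_ids <- c(sprintf("fam%02d", seq_len(nb)), "famq")
  lens <- c(sample(config$background_len_range[1L]:config$background_len_range[2L],
                   nb, replace = TRUE), config$ancestral_query_len)
  anc_seqs <- stats::setNames(vapply(lens, random_protein, ""), fam_ids)
  mid <- nb %/% 2L
  anc_order <- c(fam_ids[seq_len(mid)], "famq", fam_ids[(mid + 1L):nb])

  # genome state: list of scaffolds; each scaffold an ordered data.frame of
  # (family, track) plus a named list of sequences keyed by family:track
  gene_key <- function(family, track) paste(family, track, sep = ":")
  anc_state <- list(
    scaffolds = list(sc1 = data.frame(family = anc_order, track = "anc",
                                      stringsAsFactors = FALSE)),
    seqs = stats::setNames(as.list(anc_seqs[anc_order]),
                           gene_key(anc_order, "anc")))

  children <- function(node) tree$edge[tree$edge[, 1L] == node, 2L]
  branch_len <- function(node) tree$edge.length[tree$edge[, 2L] == node]

  apply_wgd <- function(state) {
    scaffolds <- list()
    seqs <- list()
    for (sc in names(state$scaffolds)) {
      g <- state$scaffolds[[sc]]
      ga <- data.frame(family = g$family, track = "A", stringsAsFactors = FALSE)
      gb <- data.frame(family = g$family, track = "B", stringsAsFactors = FALSE)
      scaffolds[[paste0(sc, "a")]] <- ga
      scaffolds[[paste0(sc, "b")]] <- gb
      old <- gene_key(g$family, g$track)
      seqs[gene_key(g$family, "A")] <- state$seqs[old]
      seqs[gene_key(g$family, "B")] <- state$seqs[old]
    }
    list(scaffolds = scaffolds, seqs = seqs)
  }

  evolve_state <- function(state, t) {
    prefix <- config$conserved_prefix_len
    state$seqs <- lapply(stats::setNames(names(state$seqs), names(state$seqs)),
                         function(k) {
      fam <- sub(":.*$", "", k)
      evolve_sequence(state$seqs[[k]], t, config$sub_rate, config$indel_rate,
                      if (fam == "famq") prefix else 0L)
    })
    if (config$shuffle_rate > 0) {
      for (sc in names(state$scaffolds)) {
        n_ev <- stats::rpois(1L, config$shuffle_rate)
        if (n_ev > 0L) {
          ord <- seq_len(nrow(state$scaffolds[[sc]]))
          for (e in seq_len(n_ev)) ord <- shuffle_order(ord)
          state$scaffolds[[sc]] <- state$scaffolds[[sc]][ord, , drop = FALSE]
        }
      }
    }
    state
  }

  leaves <- list()
  walk <- function(node, state) {
    kids <- children(node)
    if (!length(kids)) {
      leaves[[tree$tip.label[node]]] <<- state
      return(invisible())
    }
    for (kid in kids) {
      st <- state
      if (kid == wgd_node) st <- apply_wgd(st)
      st <- evolve_state(st, branch_len(kid))
      walk(kid, st)
    }
  }
  root <- ntip + 1L
  walk(root, anc_state)

  post_tips <- tree$tip.label[bfs_descendant_tips(tree, wgd_node)]
  genomes <- list()
  truth_membership <- character(); truth_sublineage <- character()
  ohno <- list(); anc_rows <- list()

  for (tip in tree$tip.label) {
    state <- leaves[[tip]]
    is_post <- tip %in% post_tips
    code <- check_species_code(tip)
    orf_rows <- list(); seqs_out <- character()
    pending_ohno <- list()
    for (sc in names(state$scaffolds)) {
      g <- state$scaffolds[[sc]]
      if (is_post) {
        # per-leaf retention draw: drop each duplicated copy with
        # 1 - retention_prob; resolved jointly across paired scaffolds below
        # so that no family ever loses both copies
        g$keep <- stats::runif(nrow(g)) < config$retention_prob
      }
      orf_rows[[sc]] <- g
    }
    # retention decided jointly across the paired scaffolds
    if (is_post) {
      for (sc in names(state$scaffolds)) {
        if (!endsWith(sc, "a")) next
        scb <- sub("a$", "b", sc)
        ga <- orf_rows[[sc]]; gb <- orf_rows[[scb]]
        for (fam in unique(c(ga$family, gb$family))) {
          ia <- which(ga$family == fam); ib <- which(gb$family == fam)
          if (length(ia) && length(ib) && !ga$keep[ia] && !gb$keep[ib]) {
            if (stats::runif(1L) < 0.5) ga$keep[ia] <- TRUE else gb$keep[ib] <- TRUE
          }
        }
        orf_rows[[sc]] <- ga[ga$keep, c("family", "track"), drop = FALSE]
        orf_rows[[scb]] <- gb[gb$keep, c("family", "track"), drop = FALSE]
      }
    }
    for (sc in names(orf_rows)) {
      g <- orf_rows[[sc]]
      if (!nrow(g)) next
      local <- sprintf("%sg%02d", sc, seq_len(nrow(g)))
      ids <- canonical_orf_id(code, 1L, local)
      sq <- vapply(gene_key(g$family, g$track), function(k) state$seqs[[k]], "")
      if (is_post) {
        qb <- which(g$family == "famq" & g$track == "B")
        if (length(qb))
          sq[qb] <- apply_truncation(sq[qb], config$truncation_target_range,
                                     config$conserved_prefix_len)
      }
      names(sq) <- ids
      seqs_out <- c(seqs_out, sq)
      orf_rows[[sc]] <- data.frame(orf_id = ids, scaffold_id = sc,
                                   ordinal = seq_len(nrow(g)) - 1L,
                                   strand = "+", length = nchar(sq),
                                   family = g$family, track = g$track,
                                   stringsAsFactors = FALSE)
    }
    orf_rows <- orf_rows[vapply(orf_rows, is.data.frame, TRUE)]
    orfs <- do.call(rbind, orf_rows)
    rownames(orfs) <- NULL
    truth_membership[orfs$orf_id] <- orfs$family
    isq <- orfs$family == "famq"
    truth_sublineage[orfs$orf_id[isq]] <-
      ifelse(rep(is_post, sum(isq)),
             ifelse(orfs$track[isq] == "B", "CUP2-like", "HAA1-like"),
             "PROTOPLOID")
    if (is_post) {
      for (fam in unique(orfs$family)) {
        ids <- orfs$orf_id[orfs$family == fam]
        if (length(ids) == 2L) {
          tr <- orfs$track[match(ids, orfs$orf_id)]
          ohno[[length(ohno) + 1L]] <- data.frame(
            orf_a = ids[tr == "A"], orf_b = ids[tr == "B"], family = fam,
            species_code = code, stringsAsFactors = FALSE)
        }
      }
    }
    anc_rows[[tip]] <- orfs[, c("orf_id", "family", "track", "scaffold_id",
                                "ordinal")]
    rec_orfs <- orfs[, c("orf_id", "scaffold_id", "ordinal", "strand", "length")]
    genomes[[tip]] <- new_genome_record(code, 1L,
                                        if (is_post) "post" else "pre",
                                        rec_orfs, seqs_out[rec_orfs$orf_id])
  }

  db <- compile_db(genomes)
  ohnolog_pairs <- do.call(rbind, c(ohno, list(data.frame(
    orf_a = character(), orf_b = character(), family = character(),
    species_code = character(), stringsAsFactors = FALSE))))
  truth <- list(family_membership = truth_membership,
                ohnolog_pairs = ohnolog_pairs,
                sublineage = truth_sublineage,
                ancestral_order = do.call(rbind, anc_rows))
  rownames(truth$ancestral_order) <- NULL
  structure(list(db = db, truth = truth, config = config),
            class = "wgd_simulation")
}

# tip indices below a node (the node's clade)
bfs_descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  acc <- integer()
  stack <- node
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (v <= ntip) acc <- c(acc, v)
    else stack <- c(stack, tree$edge[tree$edge[, 1L] == v, 2L])
  }
  sort(acc)
}

#' @export
print.wgd_simulation <- function(x, ...) {
  cat("WGD genome-evolution simulation (seed", x$config$seed, ")\n")
  print(x$db)
  cat("  query-family copies:", sum(x$truth$family_membership == "famq"), "\n")
  cat("  ohnolog pairs:", nrow(x$truth$ohnolog_pairs), "\n")
  invisible(x)
}

#' Write simulation truth tables as TSV
#'
#' @param sim a `wgd_simulation`.
#' @param dir output directory.
#' @export
write_truth_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(orf_id = names(sim$truth$family_membership),
                       family = unname(sim$truth$family_membership)),
            file.path(dir, "family_membership.tsv"))
  write_tsv(sim$truth$ohnolog_pairs, file.path(dir, "ohnolog_pairs.tsv"))
  write_tsv(data.frame(orf_id = names(sim$truth$sublineage),
                       sublineage = unname(sim$truth$sublineage)),
            file.path(dir, "sublineage.tsv"))
  write_tsv(sim$truth$ancestral_order, file.path(dir, "ancestral_order.tsv"))
  invisible(dir)
}
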