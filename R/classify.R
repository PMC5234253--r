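#' Pairwise identity distances among family members
#'
#' Distance `d(i, j) = 1 - identity_pct(i, j) / 100` from global
#' Needleman--Wunsch alignment over all alignment columns. The matrix is
#' symmetric with a zero diagonal.
#'
#' @param member_ids character vector (>= 2) of ORF ids present in `db`.
#' @param db a `genome_db`.
#' @param scores scoring scheme for [align_global()].
#' @return symmetric numeric matrix with `member_ids` dimnames.
#' @export
pairwise_distances <- function(member_ids, db, scores = alignment_params()) {
  member_ids <- unique(as.character(member_ids))
  if (length(member_ids) < 2L) stop2("need >= 2 members")
  missing <- setdiff(member_ids, names(db$seqs))
  if (length(missing)) stop2("unknown orf_id: ", missing[1L])
  n <- length(member_ids)
  d <- matrix(0, n, n, dimnames = list(member_ids, member_ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- align_global(db$seqs[[member_ids[i]]], db$seqs[[member_ids[j]]], scores)
      d[i, j] <- d[j, i] <- 1 - r$identity_pct / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Desk-scale phylogenetic stand-in: builds an unrooted binary
#' neighbor-joining tree whose leaf set equals the matrix ids. On an additive
#' (tree-metric) matrix the output topology induces the generating tree. The
#' Newick text can seed external Bayesian/ML analyses, which this package does
#' not perform.
#'
#' @param dm symmetric non-negative matrix with zero diagonal and >= 3 taxa.
#' @return Newick text (character scalar).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop2("dm must be a square matrix")
  if (nrow(dm) < 3L) stop2("need >= 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop2("dm must be symmetric")
  if (any(diag(dm) != 0)) stop2("dm must have a zero diagonal")
  tr <- ape::nj(dm)
  ape::write.tree(tr)
}

ROLE_LEVELS <- c("HAA1_orthologue", "CUP2_orthologue", "PROTOPLOID_single",
                 "OUTGROUP")

#' Assign orthologue roles from protein length and WGD taxonomy
#'
#' Implements the length/taxonomy classification criteria: members from
#' pre-WGD (protoploid) genomes are single ancestral-type copies; members from
#' post-WGD genomes are split by protein length -- shorter than
#' `length_cutoff` amino acids means the size-reduced Cup2-type orthologue,
#' otherwise the full-length Haa1-type orthologue. The default cutoff of 450
#' aa splits the empirical length gap between the short cluster (221--356 aa)
#' and the full-length clusters (>= 525 aa). A user-designated outgroup id can
#' be excluded from the roles.
#'
#' @param member_ids family member ORF ids.
#' @param db a `genome_db` supplying lengths and pre/post-WGD flags; may be
#'   omitted when `lengths` and `wgd_flags` are given directly.
#' @param lengths optional named numeric vector of protein lengths.
#' @param wgd_flags optional named character vector (`"pre"`/`"post"`).
#' @param length_cutoff length threshold in amino acids (default 450).
#' @param outgroup optional character vector of ids to label `OUTGROUP`.
#' @return data.frame with columns `orf_id`, `species_code`, `wgd_status`,
#'   `length`, `role`; every member receives exactly one role.
#' @export
assign_roles <- function(member_ids, db = NULL, lengths = NULL,
                         wgd_flags = NULL, length_cutoff = 450L,
                         outgroup = NULL) {
  member_ids <- as.character(member_ids)
  if (!is.null(db)) {
    i <- match(member_ids, db$orf_table$orf_id)
    if (anyNA(i)) stop2("unknown orf_id: ", member_ids[which(is.na(i))[1L]])
    lengths <- db$orf_table$length[i]
    wgd_flags <- db$orf_table$wgd_status[i]
    species <- db$orf_table$species_code[i]
  } else {
    if (is.null(lengths) || is.null(wgd_flags))
      stop2("supply db, or lengths and wgd_flags")
    pick <- function(v) if (!is.null(names(v))) unname(v[member_ids]) else unname(v)
    lengths <- pick(lengths)
    wgd_flags <- pick(wgd_flags)
    species <- substr(member_ids, 1L, 4L)
  }
  if (anyNA(wgd_flags) || !all(wgd_flags %in% c("pre", "post")))
    stop2("missing or invalid pre/post-WGD flag")
  role <- ifelse(wgd_flags == "pre", "PROTOPLOID_single",
                 ifelse(lengths < length_cutoff, "CUP2_orthologue",
                        "HAA1_orthologue"))
  if (!is.null(outgroup)) role[member_ids %in% outgroup] <- "OUTGROUP"
  data.frame(orf_id = member_ids, species_code = species,
             wgd_status = wgd_flags, length = as.integer(lengths),
             role = role, stringsAsFactors = FALSE)
}

#' Per-role protein length statistics
#'
#' @param roles data.frame from [assign_roles()].
#' @return data.frame with one row per role: n, length_min, length_mean,
#'   length_max.
#' @export
role_length_summary <- function(roles) {
  sp <- split(roles$length, roles$role)
  out <- data.frame(role = names(sp),
                    n = vapply(sp, length, 1L),
                    length_min = vapply(sp, min, 1),
                    length_mean = vapply(sp, mean, 1),
                    length_max = vapply(sp, max, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write the cluster/role report TSV
#'
#' @param roles data.frame from [assign_roles()].
#' @param path output path.
#' @param cluster_labels optional named vector of phylogenetic cluster labels.
#' @export
write_cluster_report <- function(roles, path, cluster_labels = NULL) {
  tab <- roles
  tab$cluster_label <- if (is.null(cluster_labels)) NA_character_
                       else unname(cluster_labels[tab$orf_id])
  write_tsv(tab[, c("orf_id", "cluster_label", "role", "length",
                    "species_code", "wgd_status")], path)
}
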