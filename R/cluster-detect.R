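# T6SS gene-cluster calling. A cluster is a maximal run of core-labelled
# genes in which adjacent core genes are separated by at most `max_gap`
# non-core genes, retained when it carries at least `min_core` DISTINCT
# core families (tandem copies of one family never satisfy the rule).
# The cluster gene list spans first to last core gene, inclusive of the
# intervening non-core genes.

#' Scan one contig for T6SS gene clusters
#'
#' @param genes Gene table of one contig, sorted by start (see
#'   [contig_genes()]).
#' @param family_map A `family_map` covering the contig's genes.
#' @param min_core Minimum number of distinct core families (default 4).
#' @param max_gap Maximum number of consecutive non-core genes between
#'   adjacent core genes in a cluster (default 10).
#' @param genome_id Genome id stamped onto the clusters.
#' @return `data.frame` of clusters with list-columns `gene_ids`,
#'   `core_present`, `accessory`, `flanking_accessory`; columns
#'   `span_start`/`span_end` (0-based half-open bp), `core_count`,
#'   `truncated` (`none`/`left`/`right`/`both`), `complete`.
#' @export
scan_contig <- function(genes, family_map, min_core = 4, max_gap = 10,
                        genome_id = "") {
  empty <- empty_clusters()
  if (!nrow(genes)) return(empty)
  core <- unname(family_map$core[genes$gene_id])
  runs <- core_runs(ifelse(is.na(core), "", core), min_core, max_gap)
  if (!length(runs)) return(empty)
  out <- lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    idx <- r$first:r$last
    fams <- core[idx]
    fams <- sort(unique(fams[!is.na(fams)]))
    ids <- genes$gene_id[idx]
    acc <- accessory_in(family_map, ids)
    # flanking accessory: within max_gap genes beyond the outermost cores
    left_idx <- seq(max(1L, r$first - max_gap), r$first - 1L)
    right_idx <- seq(r$last + 1L, min(nrow(genes), r$last + max_gap))
    left_idx <- left_idx[left_idx >= 1 & left_idx < r$first]
    right_idx <- right_idx[right_idx > r$last & right_idx <= nrow(genes)]
    flank_acc <- accessory_in(family_map, genes$gene_id[c(left_idx, right_idx)])
    complete <- length(fams) == 13L
    gap_left <- r$first - 1L          # genes between cluster and contig start
    gap_right <- nrow(genes) - r$last # genes between cluster and contig end
    trunc <- "none"
    if (!complete) {
      l <- gap_left < max_gap
      rg <- gap_right < max_gap
      trunc <- if (l && rg) "both" else if (l) "left" else if (rg) "right" else "none"
    }
    data.frame(
      cluster_id = sprintf("%s|%s|%d", genome_id, genes$contig_id[[1]], k),
      genome_id = genome_id,
      contig_id = genes$contig_id[[1]],
      span_start = min(genes$start[idx]),
      span_end = max(genes$end[idx]),
      core_count = length(fams),
      complete = complete,
      truncated = trunc,
      gene_ids = I(list(ids)),
      core_present = I(list(fams)),
      accessory = I(list(acc)),
      flanking_accessory = I(list(flank_acc)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

empty_clusters <- function() {
  data.frame(cluster_id = character(), genome_id = character(),
             contig_id = character(), span_start = integer(),
             span_end = integer(), core_count = integer(),
             complete = logical(), truncated = character(),
             gene_ids = I(list()), core_present = I(list()),
             accessory = I(list()), flanking_accessory = I(list()),
             stringsAsFactors = FALSE)
}

# Segment the positions of core-labelled genes into maximal runs where
# adjacent cores are separated by <= max_gap non-core genes; keep runs with
# >= min_core distinct families. fam is "" for non-core genes.
core_runs <- function(fam, min_core, max_gap) {
  pos <- which(nzchar(fam))
  if (!length(pos)) return(list())
  brk <- which(diff(pos) - 1L > max_gap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(pos))
  runs <- list()
  for (s in seq_along(starts)) {
    p <- pos[starts[s]:ends[s]]
    if (length(unique(fam[p])) >= min_core) {
      runs[[length(runs) + 1L]] <- list(first = p[[1]], last = p[[length(p)]])
    }
  }
  runs
}

accessory_in <- function(family_map, gene_ids) {
  a <- family_map$accessory
  a <- a[a$gene_id %in% gene_ids, , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Scan a whole genome for T6SS clusters
#'
#' @param genome An `annotated_genome`.
#' @param family_map Its `family_map`.
#' @inheritParams scan_contig
#' @return Cluster table (see [scan_contig()]) over all contigs.
#' @export
scan_genome <- function(genome, family_map, min_core = 4, max_gap = 10) {
  res <- lapply(genome$contigs$contig_id, function(cid) {
    scan_contig(contig_genes(genome, cid), family_map,
                min_core = min_core, max_gap = max_gap,
                genome_id = genome$genome_id)
  })
  out <- do.call(rbind, c(res, list(empty_clusters())))
  rownames(out) <- NULL
  out
}

#' Completeness record of one called cluster
#'
#' Lists present and missing core families, accessory genes by family, and
#' attributes incompleteness to an assembly break when the cluster is
#' truncated at a contig end, otherwise to genuine absence.
#'
#' @param cluster One row of a cluster table.
#' @return List with `core_present`, `missing`, `complete`,
#'   `accessory_by_family`, and `cause`
#'   (`NA`/`truncated_assembly`/`genuinely_absent`).
#' @export
classify_completeness <- function(cluster) {
  present <- cluster$core_present[[1]]
  missing <- setdiff(t6ss_core_families(), present)
  acc <- cluster$accessory[[1]]
  by_fam <- if (nrow(acc)) split(acc$gene_id, acc$family) else list()
  cause <- if (cluster$complete) NA_character_
  else if (cluster$truncated != "none") "truncated_assembly"
  else "genuinely_absent"
  list(cluster_id = cluster$cluster_id,
       core_present = present, missing = missing,
       complete = cluster$complete,
       accessory_by_family = by_fam,
       cause = cause)
}

#' Label clusters as known systems (T6SS1/T6SS2)
#'
#' When a replicon map (contig id -> chromosome number) is provided,
#' clusters are labelled `T6SS1`/`T6SS2` by replicon; otherwise, when
#' subtype assignments and a subtype -> system map are given, by subtype.
#' Conflicting evidence yields `unlabeled` with a warning; multiple
#' clusters on one replicon get ordinal suffixes.
#'
#' @param clusters Cluster table.
#' @param replicon_map Named character/integer, contig id -> chromosome
#'   (1 or 2), or `NULL`.
#' @param subtypes Optional `data.frame` with `cluster_id`, `subtype`.
#' @param subtype_system_map Named character, subtype token -> system
#'   label.
#' @return The cluster table with a `system_label` column.
#' @export
label_known_systems <- function(clusters, replicon_map = NULL,
                                subtypes = NULL, subtype_system_map = NULL) {
  if (!nrow(clusters)) {
    clusters$system_label <- character(0)
    return(clusters)
  }
  lab_rep <- rep(NA_character_, nrow(clusters))
  if (!is.null(replicon_map)) {
    hit <- clusters$contig_id %in% names(replicon_map)
    lab_rep[hit] <- paste0("T6SS", replicon_map[clusters$contig_id[hit]])
  }
  lab_sub <- rep(NA_character_, nrow(clusters))
  if (!is.null(subtypes) && !is.null(subtype_system_map)) {
    m <- match(clusters$cluster_id, subtypes$cluster_id)
    st <- subtypes$subtype[m]
    known <- !is.na(st) & st %in% names(subtype_system_map)
    lab_sub[known] <- unname(subtype_system_map[st[known]])
  }
  lab <- ifelse(is.na(lab_rep), lab_sub, lab_rep)
  conflict <- !is.na(lab_rep) & !is.na(lab_sub) & lab_rep != lab_sub
  if (any(conflict)) {
    warning(sprintf("%d cluster(s) with conflicting replicon/subtype labels set to unlabeled",
                    sum(conflict)), call. = FALSE)
    lab[conflict] <- "unlabeled"
  }
  lab[is.na(lab)] <- "unlabeled"
  # ordinal suffixes when one genome carries several clusters with one label
  key <- paste(clusters$genome_id, lab)
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (lab[idx[1]] != "unlabeled" && length(idx) > 1) {
      lab[idx] <- paste0(lab[idx], ".", seq_along(idx))
    }
  }
  clusters$system_label <- lab
  clusters
}
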