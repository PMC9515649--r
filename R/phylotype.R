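# Sheath (TssB+TssC) phylotyping: extract the concatenated sheath-subunit
# sequence per cluster, build an identity-based distance matrix from
# pairwise global alignments, reconstruct a neighbor-joining tree, and
# assign each cluster to a described T6SS subtype by nearest labelled
# reference.

# Reference median TssC length used to pick among multiple tssC copies.
TSSC_REF_LEN <- 506L
TSSB_REF_LEN <- 170L

#' Extract the concatenated TssB+TssC sheath sequence of a cluster
#'
#' Concatenation order is fixed as TssB then TssC. When a cluster carries
#' several copies of a sheath gene, the copy whose length is closest to the
#' reference median (TssC 506 aa, TssB 170 aa) is used and the choice is
#' logged via `message()`. A cluster lacking either subunit yields `NULL`
#' with a logged reason.
#'
#' @param cluster One row of a cluster table.
#' @param genome The `annotated_genome` the cluster was called on.
#' @param family_map Its `family_map`.
#' @return A `sheath_sequence` (list with `cluster_id`, `tssB_seq`,
#'   `tssC_seq`, `concatenated`, `tssB_gene`, `tssC_gene`) or `NULL`.
#' @export
extract_sheath <- function(cluster, genome, family_map) {
  ids <- cluster$gene_ids[[1]]
  core <- family_map$core[ids]
  pick <- function(fam, ref_len) {
    cand <- ids[!is.na(core) & core == fam]
    if (!length(cand)) return(NULL)
    seqs <- genome$genes$protein_seq[match(cand, genome$genes$gene_id)]
    keep <- nzchar(seqs)
    cand <- cand[keep]; seqs <- seqs[keep]
    if (!length(cand)) return(NULL)
    if (length(cand) > 1) {
      i <- order(abs(nchar(seqs) - ref_len), cand)[[1]]
      message(sprintf("cluster %s: %d %s copies; using %s (%d aa, closest to %d aa reference)",
                      cluster$cluster_id, length(cand), fam, cand[[i]],
                      nchar(seqs[[i]]), ref_len))
    } else i <- 1L
    list(gene = cand[[i]], seq = seqs[[i]])
  }
  b <- pick("tssB", TSSB_REF_LEN)
  cc <- pick("tssC", TSSC_REF_LEN)
  if (is.null(b) || is.null(cc)) {
    message(sprintf("cluster %s excluded from sheath phylogeny: missing %s",
                    cluster$cluster_id,
                    paste(c("tssB", "tssC")[c(is.null(b), is.null(cc))],
                          collapse = " and ")))
    return(NULL)
  }
  structure(list(cluster_id = cluster$cluster_id,
                 tssB_seq = b$seq, tssC_seq = cc$seq,
                 tssB_gene = b$gene, tssC_gene = cc$gene,
                 concatenated = paste0(b$seq, cc$seq)),
            class = "sheath_sequence")
}

#' Identity-distance matrix over sheath sequences
#'
#' `d(i, j) = 1 - identity` of the pairwise global alignment of the
#' concatenated sheath sequences (alignment-column identity convention).
#'
#' @param sheaths Named character vector of concatenated sheath sequences,
#'   or a list of `sheath_sequence` objects.
#' @return A symmetric `matrix` with zero diagonal and entries in `[0, 1]`.
#' @export
sheath_distance_matrix <- function(sheaths) {
  seqs <- as_sheath_vector(sheaths)
  n <- length(seqs)
  if (n < 2) stop_bad("need at least 2 sheath sequences")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) {
    res <- align_many(seqs[[i]], seqs[(i + 1):n], type = "global")
    d[i, (i + 1):n] <- 1 - res$identity
    d[(i + 1):n, i] <- d[i, (i + 1):n]
  }
  d
}

as_sheath_vector <- function(sheaths) {
  if (is.character(sheaths)) {
    stopifnot(!is.null(names(sheaths)))
    return(sheaths)
  }
  stats::setNames(vapply(sheaths, function(s) s$concatenated, ""),
                  vapply(sheaths, function(s) s$cluster_id, ""))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (via `ape::nj`); for an additive input matrix
#' the tree's path-length matrix reproduces the input exactly. With fewer
#' than 3 taxa a degenerate single-edge tree is returned with a warning.
#'
#' @param D Symmetric distance matrix with labelled dimnames.
#' @return An unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  stopifnot(isSymmetric(unname(D)))
  n <- nrow(D)
  if (n < 2) stop_bad("need at least 2 taxa")
  if (n == 2) {
    warning("fewer than 3 taxa: returning a degenerate single-edge tree",
            call. = FALSE)
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(D[1, 2] / 2, 2),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(D))
}

#' Read labelled reference sheaths from FASTA
#'
#' Headers carry the subtype token as `subtype=<token>` after the id, e.g.
#' `>ref_s3_1 subtype=3`.
#'
#' @param path Reference FASTA.
#' @return `data.frame` with `reference_id`, `subtype`, `sequence`.
#' @export
read_reference_sheaths <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  st <- sub("^.*subtype=(\\S+).*$", "\\1", names(aa))
  if (any(st == names(aa))) stop_bad("reference header without subtype= token")
  data.frame(reference_id = ids, subtype = st,
             sequence = as.character(aa), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Assign a sheath to a T6SS subtype by nearest labelled reference
#'
#' Distance is `1 - identity` of the global alignment against each
#' reference's concatenated sheath. The query takes the subtype of the
#' nearest reference unless that distance exceeds `cutoff`, in which case
#' it is `unclassified`. Distance ties resolve to the alphabetically first
#' reference id, so the result does not depend on reference order.
#'
#' @param query_sheath A `sheath_sequence`, or a single named character.
#' @param references Reference table from [read_reference_sheaths()] (at
#'   least one labelled reference per subtype of interest).
#' @param cutoff Maximum distance for classification (default 0.7).
#' @return One-row `data.frame`: `cluster_id`, `subtype`,
#'   `nearest_reference_id`, `distance`.
#' @export
assign_subtype <- function(query_sheath, references, cutoff = 0.7) {
  if (!nrow(references)) stop_bad("empty reference set")
  q <- if (is.character(query_sheath)) query_sheath else
    stats::setNames(query_sheath$concatenated, query_sheath$cluster_id)
  refs <- stats::setNames(references$sequence, references$reference_id)
  res <- align_many(q, refs, type = "global")
  dist <- 1 - res$identity
  ord <- order(dist, res$subject_id)
  best <- ord[[1]]
  st <- if (dist[best] > cutoff) "unclassified" else
    references$subtype[match(res$subject_id[best], references$reference_id)]
  data.frame(cluster_id = names(q) %||% "query",
             subtype = st,
             nearest_reference_id = res$subject_id[best],
             distance = dist[best],
             stringsAsFactors = FALSE)
}

#' Bootstrap support for a sheath NJ tree
#'
#' Resamples alignment columns of the concatenated sheath set (sequences
#' are resampled position-wise, which is appropriate here because distances
#' come from pairwise alignment of full sequences), rebuilds the NJ tree
#' per replicate, and reports, for each internal edge of the original tree,
#' the fraction of replicates containing that bipartition.
#'
#' @param sheaths Named character of concatenated sheaths.
#' @param n_replicates Number of replicates (default 100).
#' @param seed Seed for resampling.
#' @return List with `tree` (the original NJ tree) and `support`
#'   (per-bipartition fractions from `ape::prop.clades`).
#' @export
sheath_bootstrap <- function(sheaths, n_replicates = 100, seed = 1) {
  seqs <- as_sheath_vector(sheaths)
  base_tree <- nj_tree(sheath_distance_matrix(seqs))
  maxlen <- max(nchar(seqs))
  pad <- vapply(seqs, function(s) {
    paste0(s, strrep("X", maxlen - nchar(s)))
  }, "")
  chars <- do.call(rbind, strsplit(pad, ""))
  trees <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(i) {
      cols <- sample.int(maxlen, maxlen, replace = TRUE)
      boot <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      boot <- gsub("X", "", boot)
      boot[!nzchar(boot)] <- "X"
      nj_tree(sheath_distance_matrix(stats::setNames(boot, names(seqs))))
    })
  })
  support <- ape::prop.clades(base_tree, trees, rooted = FALSE) / n_replicates
  list(tree = base_tree, support = support)
}
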