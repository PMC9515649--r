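# Genomic-island genotyping: extract the chromosomal region between two
# flanking marker genes (manA and tRNA-Gly by default), cluster island
# proteins into homolog families, build a genome x family presence/absence
# matrix, hierarchically cluster genomes into island genotypes, and label
# each genotype with a rule-based archetype.

#' Extract the genomic island between two flanking marker genes
#'
#' Flanks are located by product token (word match, case-insensitive), not
#' by coordinates, so contig reordering in draft assemblies is harmless.
#' Both flanks on one contig gives a `resolved` island; flanks on two
#' contigs with the region split by exactly one assembly break (each flank's
#' island side running to a contig edge) gives `concatenated_one_break`
#' with the genes joined in flank order; anything else is `unresolved`.
#' Island length is flank-inclusive: first base of flank A through last
#' base of flank B.
#'
#' @param genome An `annotated_genome`.
#' @param flank_a_product,flank_b_product Product tokens of the two flanks.
#' @return An `island_region`: list with `genome_id`, `flank_a_gene`,
#'   `flank_b_gene`, `gene_ids` (ordered, flank-inclusive), `length_bp`,
#'   `status`, `reason`.
#' @export
extract_island <- function(genome, flank_a_product = "manA",
                           flank_b_product = "tRNA-Gly") {
  g <- genome$genes
  find_flank <- function(token) {
    pat <- sprintf("(^|[^A-Za-z0-9])%s([^A-Za-z0-9]|$)",
                   gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", token))
    hit <- which(grepl(pat, g$product, ignore.case = TRUE))
    if (!length(hit)) return(NULL)
    g[hit[[1]], ]
  }
  fa <- find_flank(flank_a_product)
  fb <- find_flank(flank_b_product)
  unresolved <- function(reason) {
    structure(list(genome_id = genome$genome_id,
                   flank_a_gene = if (is.null(fa)) NA_character_ else fa$gene_id,
                   flank_b_gene = if (is.null(fb)) NA_character_ else fb$gene_id,
                   gene_ids = character(0), length_bp = NA_integer_,
                   status = "unresolved", reason = reason),
              class = "island_region")
  }
  if (is.null(fa)) return(unresolved(sprintf("flank '%s' not found", flank_a_product)))
  if (is.null(fb)) return(unresolved(sprintf("flank '%s' not found", flank_b_product)))

  if (fa$contig_id == fb$contig_id) {
    cg <- contig_genes(genome, fa$contig_id)
    ia <- match(fa$gene_id, cg$gene_id)
    ib <- match(fb$gene_id, cg$gene_id)
    idx <- if (ia <= ib) ia:ib else ia:ib  # descending when reversed
    ids <- cg$gene_id[idx]
    span <- range(cg$start[idx], cg$end[idx])
    return(structure(list(genome_id = genome$genome_id,
                          flank_a_gene = fa$gene_id, flank_b_gene = fb$gene_id,
                          gene_ids = ids,
                          length_bp = span[[2]] - span[[1]],
                          status = "resolved", reason = ""),
                     class = "island_region"))
  }

  # Flanks on two contigs: accept exactly one assembly break. Which side of
  # each flank the island lies on follows gene orientation, as insertion
  # sites flanked by a fixed marker/tRNA pair have a defined polarity: the
  # island runs downstream of flank A (3' per its strand) and upstream of
  # flank B. Each flank's island side must reach its contig edge.
  side_segment <- function(fl, downstream) {
    cg <- contig_genes(genome, fl$contig_id)
    i <- match(fl$gene_id, cg$gene_id)
    rightward <- xor(fl$strand == "-", downstream)
    if (rightward) list(ids = cg$gene_id[i:nrow(cg)],
                        bp = max(cg$end[i:nrow(cg)]) - cg$start[i])
    else list(ids = cg$gene_id[i:1],
              bp = fl$end - min(cg$start[1:i]))
  }
  sa <- side_segment(fa, downstream = TRUE)
  sb <- side_segment(fb, downstream = FALSE)
  ids <- c(sa$ids, rev(sb$ids))
  structure(list(genome_id = genome$genome_id,
                 flank_a_gene = fa$gene_id, flank_b_gene = fb$gene_id,
                 gene_ids = ids, length_bp = sa$bp + sb$bp,
                 status = "concatenated_one_break",
                 reason = "flanks on two contigs joined at one break"),
            class = "island_region")
}

#' Build the genome x homolog-family presence/absence matrix
#'
#' Island proteins are clustered into homolog families by greedy
#' single-linkage: proteins are processed longest-first and join the first
#' existing family whose exemplar they match at local-alignment identity
#' `>= identity_threshold` with mutual coverage `>= coverage_threshold`;
#' otherwise they found a new family. Non-coding island genes (tRNAs) are
#' grouped by product token. Every island gene lands in exactly one family.
#'
#' @param islands List of `island_region`s (resolved or concatenated ones
#'   are used; at least 2 required).
#' @param genomes Named list of the `annotated_genome`s the islands came
#'   from.
#' @param identity_threshold Minimum alignment identity (default 0.7).
#' @param coverage_threshold Minimum mutual coverage (default 0.8).
#' @return A `presence_matrix`: list with `matrix` (binary, genomes x
#'   families), `families` (`data.frame` gene-level membership),
#'   `exemplars` (named character), `prevalence` (fraction of genomes per
#'   family).
#' @export
build_presence_matrix <- function(islands, genomes, identity_threshold = 0.7,
                                  coverage_threshold = 0.8) {
  usable <- Filter(function(x) x$status != "unresolved", islands)
  if (length(usable) < 2) stop_bad("need at least 2 resolved islands")
  recs <- do.call(rbind, lapply(usable, function(isl) {
    g <- genomes[[isl$genome_id]]$genes
    m <- g[match(isl$gene_ids, g$gene_id), , drop = FALSE]
    data.frame(genome_id = isl$genome_id, gene_id = m$gene_id,
               feature_kind = m$feature_kind, product = m$product,
               protein_seq = m$protein_seq, stringsAsFactors = FALSE)
  }))
  fam_of <- character(nrow(recs))

  # non-CDS genes: one family per product token
  rna <- which(recs$feature_kind != "CDS" | !nzchar(recs$protein_seq))
  fam_of[rna] <- paste0("rna:", ifelse(nzchar(recs$product[rna]),
                                       recs$product[rna], "unannotated"))

  cds <- which(!seq_len(nrow(recs)) %in% rna)
  cds <- cds[order(-nchar(recs$protein_seq[cds]), recs$gene_id[cds])]
  exemplars <- character(0)
  for (i in cds) {
    prot <- recs$protein_seq[[i]]
    assigned <- FALSE
    if (length(exemplars)) {
      res <- align_many(prot, exemplars, type = "local")
      ok <- !is.na(res$identity) & res$identity >= identity_threshold &
        res$query_coverage >= coverage_threshold &
        res$subject_coverage >= coverage_threshold
      if (any(ok)) {
        best <- which(ok)[order(-res$identity[ok])][[1]]
        fam_of[i] <- res$subject_id[best]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      fid <- sprintf("fam%03d", length(exemplars) + 1L)
      exemplars[fid] <- prot
      fam_of[i] <- fid
    }
  }
  recs$family <- fam_of
  gids <- sort(unique(recs$genome_id))
  fams <- unique(recs$family[order(recs$family)])
  m <- matrix(0L, length(gids), length(fams), dimnames = list(gids, fams))
  m[cbind(match(recs$genome_id, gids), match(recs$family, fams))] <- 1L
  structure(list(matrix = m,
                 families = recs[, c("genome_id", "gene_id", "family", "product")],
                 exemplars = exemplars,
                 prevalence = colMeans(m)),
            class = "presence_matrix")
}

#' Cluster genomes into island genotypes
#'
#' Agglomerative clustering of the presence/absence rows (binary Jaccard
#' distance, average linkage by default). `k = "auto"` picks the number of
#' genotypes maximising the mean silhouette width over k = 2..8, computed
#' over genomes in clusters of size two or more: the silhouette of a
#' singleton cluster is conventionally 0, and scoring it would veto any
#' partition that isolates a genuinely rare genotype (rare island classes
#' are expected; one archetype here is a single-genome class).
#' Genotype indices are assigned by
#' decreasing genotype size, ties by first member id, so the labelling is
#' deterministic and independent of input row order.
#'
#' @param presence A `presence_matrix` (or plain binary matrix).
#' @param linkage Agglomeration method for `hclust` (default `"average"`).
#' @param metric Distance metric for `vegan::vegdist` (default
#'   `"jaccard"`, binary).
#' @param k Number of genotypes, or `"auto"`.
#' @return `data.frame` with `genome_id`, `genotype`; attribute
#'   `silhouette` carries the mean silhouette per candidate k when
#'   `k = "auto"`.
#' @export
cluster_genotypes <- function(presence, linkage = "average",
                              metric = "jaccard", k = "auto") {
  m <- if (inherits(presence, "presence_matrix")) presence$matrix else presence
  m <- m[order(rownames(m)), , drop = FALSE]
  n <- nrow(m)
  if (n < 2) stop_bad("need at least 2 genomes")
  d <- vegan::vegdist(m, method = metric, binary = TRUE)
  d[!is.finite(d)] <- 1   # jaccard of two empty rows is NaN: treat as identical? no - maximally ambiguous, set 1
  if (max(d) == 0) {
    warning("all genomes have identical island content: single genotype",
            call. = FALSE)
    return(data.frame(genome_id = rownames(m), genotype = 1L,
                      stringsAsFactors = FALSE))
  }
  hc <- stats::hclust(d, method = linkage)
  sil_by_k <- NULL
  if (identical(k, "auto")) {
    ks <- seq(2L, min(8L, n - 1L))
    sil_by_k <- vapply(ks, function(kk) {
      ct <- stats::cutree(hc, k = kk)
      sw <- cluster::silhouette(ct, d)
      sizes <- table(ct)
      keep <- sizes[as.character(sw[, "cluster"])] >= 2
      if (!any(keep)) return(0)
      mean(sw[keep, "sil_width"])
    }, 0)
    k <- ks[[which.max(sil_by_k)]]
    names(sil_by_k) <- ks
  }
  ct <- stats::cutree(hc, k = k)
  # deterministic genotype numbering: by size desc, then first member id
  tab <- split(names(ct), ct)
  ord <- order(-lengths(tab), vapply(tab, function(x) sort(x)[[1]], ""))
  relabel <- stats::setNames(seq_along(tab), names(tab)[ord])
  out <- data.frame(genome_id = rownames(m),
                    genotype = unname(relabel[as.character(ct)]),
                    stringsAsFactors = FALSE)
  attr(out, "silhouette") <- sil_by_k
  attr(out, "k") <- as.integer(k)
  out
}

#' Label island genotypes with rule-based archetypes
#'
#' Per member island: contains a complete T6SS cluster ->
#' `complete_T6SS2_plus_genes`; contains an incomplete cluster ->
#' `incomplete_T6SS2_plus_genes`; no cluster and more than `min_genes`
#' non-flank genes -> `no_T6SS2_with_genes`; otherwise `near_empty`.
#' A genotype takes the majority archetype of its members and is flagged
#' when members disagree.
#'
#' @param genotypes Output of [cluster_genotypes()].
#' @param islands Named list of `island_region`s by genome id.
#' @param clusters Cluster table from [scan_genome()] over all genomes.
#' @param min_genes Non-flank gene count separating `no_T6SS2_with_genes`
#'   from `near_empty` (default 3).
#' @return `data.frame` with `genotype`, `archetype`, `n_members`,
#'   `mixed` (members disagreed).
#' @export
label_archetype <- function(genotypes, islands, clusters, min_genes = 3) {
  member_arch <- vapply(genotypes$genome_id, function(gid) {
    isl <- islands[[gid]]
    if (is.null(isl) || isl$status == "unresolved") return(NA_character_)
    cl <- clusters[clusters$genome_id == gid, , drop = FALSE]
    in_island <- vapply(seq_len(nrow(cl)), function(i) {
      all(cl$gene_ids[[i]] %in% isl$gene_ids)
    }, TRUE)
    cl <- cl[in_island, , drop = FALSE]
    if (nrow(cl) && any(cl$complete)) return("complete_T6SS2_plus_genes")
    if (nrow(cl)) return("incomplete_T6SS2_plus_genes")
    n_nonflank <- length(setdiff(isl$gene_ids,
                                 c(isl$flank_a_gene, isl$flank_b_gene)))
    if (n_nonflank > min_genes) "no_T6SS2_with_genes" else "near_empty"
  }, "")
  out <- do.call(rbind, lapply(split(seq_len(nrow(genotypes)),
                                     genotypes$genotype), function(idx) {
    a <- member_arch[idx]
    a <- a[!is.na(a)]
    tab <- sort(table(a), decreasing = TRUE)
    data.frame(genotype = genotypes$genotype[idx[[1]]],
               archetype = if (length(tab)) names(tab)[[1]] else NA_character_,
               n_members = length(idx),
               mixed = length(tab) > 1,
               stringsAsFactors = FALSE)
  }))
  if (any(out$mixed)) {
    warning(sprintf("%d genotype(s) with mixed member archetypes; majority label used",
                    sum(out$mixed)), call. = FALSE)
  }
  rownames(out) <- NULL
  out[order(out$genotype), ]
}
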