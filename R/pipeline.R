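# End-to-end orchestration: read genomes, assign families, call clusters,
# phylotype sheaths, genotype the genomic island, classify architectures,
# screen effectors, and write the report set. Also the ANI species
# assignment utility (the ANI table itself is an input).

#' Build a validated run configuration
#'
#' All stage thresholds with their defaults; every value is echoed into the
#' run manifest.
#'
#' @param input_dir Directory holding `<genome>.gff/.fna/.faa` triplets and
#'   the set-level files (`hits.domtbl`, `reference_sheaths.faa`,
#'   `effector_db.faa`, optional `replicons.tsv`).
#' @param out_dir Report output directory.
#' @param min_core,max_gap Cluster-calling rule (defaults 4 and 10).
#' @param domtbl_max_evalue Hit-table inclusion threshold.
#' @param subtype_cutoff Maximum sheath distance for subtype assignment.
#' @param island_identity,island_coverage Homolog-family thresholds.
#' @param linkage,metric,k Genotype clustering parameters.
#' @param min_genes Archetype rule threshold.
#' @param flank_a,flank_b Island flank product tokens.
#' @param effector_min_identity,effector_max_evalue Effector screen
#'   thresholds.
#' @param build_tree Build the sheath NJ tree (default TRUE).
#' @param seed Run seed.
#' @return A `run_config` list.
#' @export
run_config <- function(input_dir, out_dir,
                       min_core = 4L, max_gap = 10L,
                       domtbl_max_evalue = 1e-5,
                       subtype_cutoff = 0.7,
                       island_identity = 0.7, island_coverage = 0.8,
                       linkage = "average", metric = "jaccard", k = "auto",
                       min_genes = 3L,
                       flank_a = "manA", flank_b = "tRNA-Gly",
                       effector_min_identity = 0.30,
                       effector_max_evalue = 1e-6,
                       build_tree = TRUE,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run every pipeline stage over a genome set
#'
#' Stages run in order (io, family assignment, cluster detection,
#' phylotyping, island genotyping, architecture/effectors, reports). A
#' failure in one genome is isolated: the genome is dropped with its error
#' recorded in the per-genome status table and the run continues.
#'
#' @param config A `run_config`.
#' @return The result bundle (invisibly written to `config$out_dir` via
#'   [write_reports()]): list with `genomes`, `family_maps`, `clusters`,
#'   `subtypes`, `tree`, `islands`, `islands_table`, `presence`,
#'   `genotypes`, `archetypes`, `repertoires`, `fusion_reports`,
#'   `effectors`, `status`, `config`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gff <- sort(list.files(config$input_dir, pattern = "\\.gff3?$",
                         full.names = TRUE))
  if (!length(gff)) stop_bad("no GFF genomes found in %s", config$input_dir)
  status <- list()
  genomes <- list()
  for (p in gff) {
    gid <- sub("\\.gff3?$", "", basename(p))
    res <- tryCatch({
      g <- read_gff_genome(p, sub("\\.gff3?$", ".fna", p),
                           sub("\\.gff3?$", ".faa", p), genome_id = gid)
      genomes[[gid]] <- g
      "ok"
    }, error = function(e) paste("io_error:", conditionMessage(e)))
    status[[gid]] <- res
  }
  if (!length(genomes)) stop_bad("zero parseable genomes")

  hits_path <- file.path(config$input_dir, "hits.domtbl")
  all_hits <- if (file.exists(hits_path)) {
    load_domtbl(hits_path, max_evalue = config$domtbl_max_evalue)
  } else empty_hits()

  replicon_path <- file.path(config$input_dir, "replicons.tsv")
  replicon_map <- NULL
  if (file.exists(replicon_path)) {
    rm_df <- utils::read.delim(replicon_path, stringsAsFactors = FALSE)
    replicon_map <- stats::setNames(rm_df$chromosome, rm_df$contig_id)
  }

  family_maps <- list(); clusters <- list()
  sheaths <- list(); repertoires <- list(); fusion_reports <- list()
  for (gid in names(genomes)) {
    res <- tryCatch({
      g <- genomes[[gid]]
      fm <- assign_families(g, all_hits[all_hits$gene_id %in% g$genes$gene_id, ])
      family_maps[[gid]] <- fm
      cl <- scan_genome(g, fm, min_core = config$min_core,
                        max_gap = config$max_gap)
      cl <- label_known_systems(cl, replicon_map = replicon_map)
      clusters[[gid]] <- cl
      prot <- stats::setNames(g$genes$protein_seq, g$genes$gene_id)
      arch <- scan_architectures(fm)
      for (i in seq_len(nrow(cl))) {
        sh <- suppressMessages(extract_sheath(cl[i, ], g, fm))
        if (!is.null(sh)) sheaths[[cl$cluster_id[[i]]]] <- sh
        rep_call <- classify_repertoire(cl[i, ], arch, prot)
        repertoires[[cl$cluster_id[[i]]]] <- rep_call
        if (rep_call$pattern == "fusion") {
          fus <- arch[[rep_call$fusions[[1]]]]
          fusion_reports[[cl$cluster_id[[i]]]] <-
            domain_identity_report(fus, prot, arch)
        }
      }
      "ok"
    }, error = function(e) paste("detect_error:", conditionMessage(e)))
    if (res != "ok") status[[gid]] <- res
  }
  cluster_tab <- do.call(rbind, c(unname(clusters), list(empty_clusters())))
  if (!"system_label" %in% names(cluster_tab)) {
    cluster_tab$system_label <- character(0)
  }

  # phylotyping
  refs_path <- file.path(config$input_dir, "reference_sheaths.faa")
  subtypes <- NULL; tree <- NULL
  if (file.exists(refs_path) && length(sheaths)) {
    refs <- read_reference_sheaths(refs_path)
    subtypes <- do.call(rbind, lapply(sheaths, assign_subtype,
                                      references = refs,
                                      cutoff = config$subtype_cutoff))
    rownames(subtypes) <- NULL
    if (isTRUE(config$build_tree)) {
      seqs <- c(vapply(sheaths, function(s) s$concatenated, ""),
                stats::setNames(refs$sequence, refs$reference_id))
      if (length(seqs) >= 3) tree <- nj_tree(sheath_distance_matrix(seqs))
    }
  }
  if (!is.null(subtypes)) {
    cluster_tab$subtype <- subtypes$subtype[
      match(cluster_tab$cluster_id, subtypes$cluster_id)]
  }

  # island genotyping
  islands <- lapply(genomes, extract_island,
                    flank_a_product = config$flank_a,
                    flank_b_product = config$flank_b)
  islands_table <- do.call(rbind, lapply(islands, function(i)
    data.frame(genome_id = i$genome_id, status = i$status,
               n_genes = length(i$gene_ids),
               length_bp = i$length_bp %||% NA_integer_,
               reason = i$reason, stringsAsFactors = FALSE)))
  rownames(islands_table) <- NULL
  usable <- Filter(function(x) x$status != "unresolved", islands)
  presence <- NULL; genotype_df <- NULL; archetypes <- NULL
  if (length(usable) >= 2) {
    presence <- build_presence_matrix(usable, genomes,
                                      identity_threshold = config$island_identity,
                                      coverage_threshold = config$island_coverage)
    genotype_df <- cluster_genotypes(presence, linkage = config$linkage,
                                     metric = config$metric, k = config$k)
    archetypes <- label_archetype(genotype_df, islands, cluster_tab,
                                  min_genes = config$min_genes)
    # renumber genotypes in conventional archetype order (complete cluster
    # first, near-empty last), larger genotypes first within an archetype
    rank <- c(complete_T6SS2_plus_genes = 1, incomplete_T6SS2_plus_genes = 2,
              no_T6SS2_with_genes = 3, near_empty = 4)
    ord <- order(rank[archetypes$archetype], -archetypes$n_members,
                 archetypes$genotype)
    remap <- stats::setNames(seq_along(ord), archetypes$genotype[ord])
    archetypes$genotype <- unname(remap[as.character(archetypes$genotype)])
    archetypes <- archetypes[order(archetypes$genotype), ]
    rownames(archetypes) <- NULL
    genotype_df$genotype <- unname(remap[as.character(genotype_df$genotype)])
    genotype_df <- merge(genotype_df, archetypes[, c("genotype", "archetype")],
                         by = "genotype", sort = FALSE)
    genotype_df$island_status <- vapply(genotype_df$genome_id, function(g)
      islands[[g]]$status, "")
    genotype_df$island_length_bp <- vapply(genotype_df$genome_id, function(g)
      as.integer(islands[[g]]$length_bp), 0L)
    genotype_df <- genotype_df[order(genotype_df$genotype,
                                     genotype_df$genome_id),
                               c("genome_id", "genotype", "archetype",
                                 "island_status", "island_length_bp")]
    rownames(genotype_df) <- NULL
  }

  # effector screen
  db_path <- file.path(config$input_dir, "effector_db.faa")
  effectors <- NULL
  if (file.exists(db_path)) {
    db <- Biostrings::readAAStringSet(db_path)
    queries <- unlist(lapply(genomes, function(g) {
      cds <- g$genes[g$genes$feature_kind == "CDS", ]
      stats::setNames(cds$protein_seq, cds$gene_id)
    }))
    names(queries) <- sub("^[^.]*\\.", "", names(queries))
    effectors <- search_effectors(queries, db,
                                  min_identity = config$effector_min_identity,
                                  max_evalue = config$effector_max_evalue)
  }

  rep_tab <- do.call(rbind, lapply(repertoires, function(r) data.frame(
    cluster_id = r$cluster_id, pattern = r$pattern,
    n_tssB_like = length(r$tssB_like), n_tssC_like = length(r$tssC_like),
    n_fusion = length(r$fusions),
    tssC_pairwise_identity = r$tssC_pairwise_identity,
    stringsAsFactors = FALSE)))
  if (!is.null(rep_tab)) rownames(rep_tab) <- NULL

  bundle <- list(genomes = genomes, family_maps = family_maps,
                 clusters = cluster_tab, subtypes = subtypes, tree = tree,
                 islands = islands, islands_table = islands_table,
                 presence = presence, genotypes = genotype_df,
                 archetypes = archetypes,
                 repertoires = rep_tab, repertoire_calls = repertoires,
                 fusion_reports = fusion_reports,
                 effectors = effectors,
                 status = data.frame(genome_id = names(status),
                                     status = unlist(status),
                                     stringsAsFactors = FALSE),
                 n_genomes = length(genomes),
                 config = config_for_manifest(config))
  write_reports(bundle, config$out_dir)
  invisible(bundle)
}

config_for_manifest <- function(config) {
  cfg <- unclass(config)
  lapply(cfg, function(x) if (is.function(x)) deparse1(x) else x)
}

#' Assign genomes to species from a pairwise ANI table
#'
#' Each query genome joins the species of the labelled reference with which
#' it shares the highest average nucleotide identity, provided that ANI
#' meets the threshold (default 95); otherwise it is unassigned. Query
#' pairs at ANI 100 are flagged as likely clones.
#'
#' @param ani `data.frame` with columns `query`, `reference`, `ani`
#'   (percent, FastANI-style long format covering both orientations).
#' @param species_of Named character: reference genome id -> species label.
#' @param threshold Assignment cutoff in ANI percent (default 95).
#' @param tolerance Maximum tolerated |ANI(a,b) - ANI(b,a)| (default 0.5).
#' @return List with `assignments` (`data.frame`: `genome`, `species`,
#'   `best_reference`, `ani`) and `clones` (`data.frame`: `genome_a`,
#'   `genome_b`).
#' @export
assign_species <- function(ani, species_of, threshold = 95, tolerance = 0.5) {
  stopifnot(all(c("query", "reference", "ani") %in% names(ani)))
  key <- paste(ani$query, ani$reference, sep = "\r")
  rev_key <- paste(ani$reference, ani$query, sep = "\r")
  m <- match(rev_key, key)
  both <- !is.na(m)
  if (any(abs(ani$ani[both] - ani$ani[m[both]]) > tolerance)) {
    stop_bad("ANI table asymmetric beyond %.1f points", tolerance)
  }
  queries <- sort(setdiff(unique(c(ani$query, ani$reference)),
                          names(species_of)))
  assignments <- do.call(rbind, lapply(queries, function(q) {
    rows <- ani[(ani$query == q & ani$reference %in% names(species_of)) |
                  (ani$reference == q & ani$query %in% names(species_of)), ]
    ref <- ifelse(rows$query == q, rows$reference, rows$query)
    agg <- tapply(rows$ani, ref, max)
    if (!length(agg)) {
      return(data.frame(genome = q, species = NA_character_,
                        best_reference = NA_character_, ani = NA_real_,
                        stringsAsFactors = FALSE))
    }
    best <- order(-agg, names(agg))[[1]]
    ok <- agg[[best]] >= threshold
    data.frame(genome = q,
               species = if (ok) unname(species_of[names(agg)[best]])
               else NA_character_,
               best_reference = names(agg)[best], ani = agg[[best]],
               stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  qq <- ani[ani$query %in% queries & ani$reference %in% queries &
              ani$ani >= 100 & ani$query < ani$reference, , drop = FALSE]
  clones <- unique(data.frame(genome_a = qq$query, genome_b = qq$reference,
                              stringsAsFactors = FALSE))
  rownames(clones) <- NULL
  list(assignments = assignments, clones = clones)
}

#' Score detected clusters against generator truth
#'
#' A detected cluster matches a planted one when genome, contig and the
#' exact ordered gene-id list agree. Also checks core-inventory equality
#' and truncation flags for matched pairs.
#'
#' @param clusters Cluster table from [run_all()]/[scan_genome()].
#' @param truth Truth list from [generate_genome_set()].
#' @return List with `precision`, `recall`, `n_detected`, `n_truth`,
#'   `core_inventory_exact` (fraction), `truncation_correct` (fraction).
#' @export
score_recovery <- function(clusters, truth) {
  truth_keys <- list()
  for (gid in names(truth$genomes)) {
    for (cl in truth$genomes[[gid]]$clusters) {
      k <- paste(gid, cl$contig_id, paste(unlist(cl$gene_ids), collapse = ","))
      truth_keys[[k]] <- cl
    }
  }
  det_keys <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    det_keys[i] <- paste(clusters$genome_id[i], clusters$contig_id[i],
                         paste(clusters$gene_ids[[i]], collapse = ","))
  }
  tp <- sum(det_keys %in% names(truth_keys))
  core_ok <- 0L; trunc_ok <- 0L
  for (i in seq_len(nrow(clusters))) {
    t <- truth_keys[[det_keys[i]]]
    if (is.null(t)) next
    if (identical(sort(unlist(t$core_present)),
                  sort(clusters$core_present[[i]]))) core_ok <- core_ok + 1L
    if (identical(t$truncated, clusters$truncated[i])) trunc_ok <- trunc_ok + 1L
  }
  list(precision = if (nrow(clusters)) tp / nrow(clusters) else NA_real_,
       recall = if (length(truth_keys)) tp / length(truth_keys) else NA_real_,
       n_detected = nrow(clusters), n_truth = length(truth_keys),
       core_inventory_exact = if (tp) core_ok / tp else NA_real_,
       truncation_correct = if (tp) trunc_ok / tp else NA_real_)
}
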