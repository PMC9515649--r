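# Synthetic annotated-genome generator. Emits multi-contig draft genomes
# with planted T6SS clusters of controlled completeness and subtype, a
# genomic island between manA and tRNA-Gly realised in five genotype
# archetypes, roseobacter-style clusters carrying a TssC_L fusion or a
# duplicated tssC, decoy genes, a family hit table, an effector database
# with planted homologs, and machine-readable ground truth. All randomness
# flows from the single config seed.

# Approximate background amino-acid frequencies (Robinson-Robinson order
# matching AA20) used for composition-matched decoys.
AA_FREQ <- c(0.078, 0.019, 0.054, 0.063, 0.039, 0.074, 0.022, 0.052, 0.057,
             0.090, 0.022, 0.045, 0.052, 0.043, 0.051, 0.071, 0.059, 0.064,
             0.013, 0.032)

#' Random protein with natural residue composition
#' @param n Length in residues.
#' @return An amino-acid string.
#' @export
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = AA_FREQ), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Substitution-only mutant at an exact target identity
#'
#' Replaces `n - round(target_identity * n)` positions of the reference
#' with a different residue, so the positional identity to the reference is
#' exactly `round(target_identity * n) / n`. When that nearest achievable
#' identity differs from the target by more than 0.01 (short sequences) a
#' message logs the value actually realised.
#'
#' @param reference Amino-acid string.
#' @param target_identity Target identity in `(0, 1]`.
#' @param seed Optional seed; `NULL` draws from the ambient RNG stream.
#' @return Mutant sequence of the same length.
#' @export
mutate_sequence <- function(reference, target_identity, seed = NULL) {
  stopifnot(target_identity > 0, target_identity <= 1)
  with_seed(seed, {
    n <- nchar(reference)
    k_mut <- n - round(target_identity * n)
    achieved <- (n - k_mut) / n
    if (abs(achieved - target_identity) > 0.01) {
      message(sprintf("target identity %.3f not achievable at length %d; using %.3f",
                      target_identity, n, achieved))
    }
    if (k_mut == 0) return(reference)
    chars <- strsplit(reference, "")[[1]]
    pos <- sample.int(n, k_mut)
    chars[pos] <- vapply(chars[pos], function(a) {
      sample(setdiff(AA20, a), 1)
    }, "")
    paste(chars, collapse = "")
  })
}

# ---- reference panel ------------------------------------------------------

# VipA/VipB domain envelopes (0-based half-open) on the panel's standard
# sheath subunits and on the composed TssC_L fusion protein.
TSSB_VIPA_ENV <- c(10L, 150L)
TSSC_VIPB_ENV <- c(50L, 480L)
TSSCL_ENVS <- data.frame(
  family = c("VipA", "VipA", "VipB"),
  ali_start = c(200L, 440L, 680L),
  ali_end = c(340L, 580L, 1110L))
TSSCL_LEN <- 1684L

#' Bundled reference protein panel for the synthetic generator
#'
#' A deterministic set of consensus-like proteins: one per core/accessory
#' family (realistic lengths, TssC fixed at 506 aa), the manA flank, shared
#' island gene pools, intra-cluster spacer genes, effector references, and
#' per-subtype TssB/TssC sheath references (subtypes 1, 2, 3, 4a, 4b, 5).
#' The panel is generated under a fixed internal seed, independent of any
#' run seed, so it is identical across sessions.
#'
#' @return List with `core`, `accessory`, `manA`, `other`, `spacer`,
#'   `effectors`, `subtype_refs` (per subtype: `tssB`, `tssC`).
#' @export
family_reference_panel <- function() {
  with_seed(105003L, {
    core_len <- c(tssA = 360L, tssB = 170L, tssC = 506L, tssD = 160L,
                  tssE = 135L, tssF = 480L, tssG = 310L, tssH = 450L,
                  tssI = 400L, tssJ = 150L, tssK = 330L, tssL = 210L,
                  tssM = 500L)
    acc_len <- c(PAAR = 120L, FHA = 230L, Pkinase = 260L, PP2C = 240L,
                 DUF4150 = 130L, tasL = 350L, tasR = 200L, vasH = 420L,
                 impE = 180L, tagF = 190L)
    gen <- function(lens) {
      stats::setNames(vapply(lens, random_protein, ""), names(lens))
    }
    other_len <- stats::setNames(
      rep(c(110L, 140L, 170L, 200L, 130L, 160L, 190L, 220L), 3),
      c(paste0("otherA", 1:8), paste0("otherB", 1:8), paste0("otherC", 1:8)))
    other_len <- c(other_len, otherE1 = 120L, otherE2 = 120L)
    subtype_refs <- lapply(
      stats::setNames(nm = c("1", "2", "3", "4a", "4b", "5")),
      function(s) list(tssB = random_protein(170L),
                       tssC = random_protein(506L)))
    list(core = gen(core_len),
         accessory = gen(acc_len),
         manA = random_protein(390L),
         other = gen(other_len),
         spacer = gen(stats::setNames(rep(130L, 6), paste0("spc", 1:6))),
         effectors = gen(stats::setNames(rep(200L, 5), paste0("eff", 1:5))),
         subtype_refs = subtype_refs)
  })
}

# ---- genome builder -------------------------------------------------------

# Mutable accumulator used while composing a synthetic genome.
new_builder <- function(genome_id, intergenic_bp = 150L) {
  env <- new.env(parent = emptyenv())
  env$genome_id <- genome_id
  env$intergenic <- intergenic_bp
  env$genes <- list(); env$hits <- list(); env$contigs <- character(0)
  env$contig_id <- NULL; env$pos <- NA_integer_; env$counter <- 0L
  env
}

b_contig <- function(b, contig_id) {
  b$contig_id <- contig_id
  b$contigs <- c(b$contigs, contig_id)
  b$pos <- 0L
  invisible(contig_id)
}

# Place one gene at the current position (or at an absolute start `at`),
# record any family / domain hits, and advance. Domains are data.frames
# with family/ali_start/ali_end relative to the protein.
b_gene <- function(b, protein, product, kind = "CDS", family = NULL,
                   domains = NULL, at = NULL, strand = "+") {
  b$counter <- b$counter + 1L
  gid <- sprintf("%s_%05d", b$genome_id, b$counter)
  len_bp <- if (kind == "CDS") 3L * (nchar(protein) + 1L) else 76L
  start <- if (is.null(at)) b$pos else as.integer(at)
  b$genes[[length(b$genes) + 1L]] <- data.frame(
    gene_id = gid, contig_id = b$contig_id,
    start = start, end = start + len_bp,
    strand = strand, feature_kind = kind, product = product,
    protein_seq = if (kind == "CDS") protein else "",
    stringsAsFactors = FALSE)
  b$pos <- start + len_bp + b$intergenic
  if (!is.null(family)) {
    for (fam in family) {
      b$hits[[length(b$hits) + 1L]] <- data.frame(
        gene_id = gid, family = fam, score = round(1.5 * nchar(protein), 1),
        evalue = 1e-60, ali_start = 0L, ali_end = nchar(protein),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(domains)) {
    for (i in seq_len(nrow(domains))) {
      b$hits[[length(b$hits) + 1L]] <- data.frame(
        gene_id = gid, family = domains$family[i],
        score = round(0.9 * (domains$ali_end[i] - domains$ali_start[i]), 1),
        evalue = 1e-40,
        ali_start = domains$ali_start[i], ali_end = domains$ali_end[i],
        stringsAsFactors = FALSE)
    }
  }
  gid
}

b_decoys <- function(b, n, len_range = c(80L, 150L)) {
  for (i in seq_len(n)) {
    b_gene(b, random_protein(sample(len_range[1]:len_range[2], 1)),
           "hypothetical protein")
  }
}

b_finish <- function(b, source = "unknown", taxon_label = "",
                     margin = 500L) {
  genes <- do.call(rbind, b$genes)
  clen <- vapply(b$contigs, function(cid) {
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    as.integer(if (nrow(g)) max(g$end) + margin else margin)
  }, 0L)
  contigs <- data.frame(contig_id = b$contigs, length = unname(clen),
                        stringsAsFactors = FALSE)
  seqs <- stats::setNames(vapply(clen, random_dna, ""), b$contigs)
  genome <- annotated_genome(b$genome_id, contigs, genes, source,
                             taxon_label, contig_seqs = seqs)
  hits <- do.call(rbind, c(b$hits, list(empty_hits())))
  list(genome = genome, hits = hits)
}

# ---- cluster planting -----------------------------------------------------

sheath_domains_for <- function(fam, plen) {
  if (fam == "tssB") {
    data.frame(family = "VipA", ali_start = TSSB_VIPA_ENV[1],
               ali_end = TSSB_VIPA_ENV[2])
  } else if (fam == "tssC" && plen == TSSCL_LEN) {
    TSSCL_ENVS
  } else if (fam == "tssC") {
    data.frame(family = "VipB", ali_start = TSSC_VIPB_ENV[1],
               ali_end = TSSC_VIPB_ENV[2])
  } else NULL
}

# Compose a TssC_L fusion from a cluster's own sheath subunits:
# two VipA copies (identities id[1], id[2] to TssB's VipA domain) and one
# VipB copy (identity id[3] to TssC's VipB domain), padded to 1,684 aa.
compose_tsscl <- function(tssB_seq, tssC_seq, identities = c(0.86, 0.26, 0.31)) {
  vipA <- substr(tssB_seq, TSSB_VIPA_ENV[1] + 1L, TSSB_VIPA_ENV[2])
  vipB <- substr(tssC_seq, TSSC_VIPB_ENV[1] + 1L, TSSC_VIPB_ENV[2])
  paste0(random_protein(200L),
         mutate_sequence(vipA, identities[1]),
         random_protein(100L),
         mutate_sequence(vipA, identities[2]),
         random_protein(100L),
         mutate_sequence(vipB, identities[3]),
         random_protein(TSSCL_LEN - 1110L))
}

#' Plant a T6SS gene cluster into a genome under construction
#'
#' Emits core genes in the canonical tssA..tssM template order (minus
#' `missing`), with accessory genes and non-core spacer/decoy genes
#' interleaved as requested, all mutated from the panel at `identity`.
#' Sheath subunits derive from `sheath_base` (a TssB/TssC pair, typically a
#' per-set mutant of a subtype reference). `sheath_pattern` optionally adds
#' a TssC_L fusion gene or a second (duplicated) tssC after the tssC gene.
#' `gaps` plants a fixed number of decoy genes after named core genes
#' (boundary-case mode: gaps of exactly 10 and 11); otherwise `gap_fun`
#' draws the intervening-gene count per junction. `truncate_after` starts a
#' new contig after the named core gene and drops `lost` families, planting
#' an assembly-broken cluster.
#'
#' @param b Internal genome builder.
#' @param panel Panel from [family_reference_panel()].
#' @param sheath_base List with `tssB`, `tssC` base sequences.
#' @param subtype Subtype token recorded in the truth.
#' @param missing Core families to omit.
#' @param accessory_inside Named character: accessory family -> core gene
#'   after which it is planted.
#' @param accessory_before,accessory_after Accessory (or island-pool)
#'   tokens planted before the first / after the last core gene.
#' @param spacers Named character: spacer token -> core gene after which it
#'   is planted (shared-family intra-cluster genes).
#' @param gaps Named integer: decoy genes planted after named core genes.
#' @param gap_fun Function drawing the decoy count per remaining junction.
#' @param identity Mutation identity to the panel (default 0.92).
#' @param sheath_pattern `"standard"`, `"fusion"`, or `"duplication"`.
#' @param fusion_identities VipA/VipA/VipB fused-domain identities.
#' @param dup_identity Identity of the duplicated tssC to the first copy.
#' @param truncate_after Core family after which the contig breaks.
#' @param next_contig_id Contig id used after the break.
#' @param lost Families dropped at the break.
#' @return Truth record: list with `contig_id`, `gene_ids` (first..last
#'   core, intervening genes included), `core_present`, `subtype`,
#'   `truncated`, `pattern`, `sheath_genes`, `fusion_identities`.
#' @export
plant_cluster <- function(b, panel, sheath_base, subtype = "1",
                          missing = character(0),
                          accessory_inside = character(0),
                          accessory_before = character(0),
                          accessory_after = character(0),
                          spacers = character(0),
                          gaps = NULL,
                          gap_fun = function() sample(0:2, 1),
                          identity = 0.92,
                          sheath_pattern = "standard",
                          fusion_identities = c(0.86, 0.26, 0.31),
                          dup_identity = 0.35,
                          truncate_after = NULL, next_contig_id = NULL,
                          lost = character(0)) {
  fams <- setdiff(t6ss_core_families(), missing)
  if (length(bad <- setdiff(missing, t6ss_core_families()))) {
    stop_bad("unknown core family in completeness spec: %s", bad[[1]])
  }
  planted <- character(0); planted_is_core <- logical(0)
  sheath_genes <- list(); tssB_seq_local <- NULL
  note <- function(gid, is_core) {
    planted <<- c(planted, gid)
    planted_is_core <<- c(planted_is_core, is_core)
  }
  emit_acc <- function(tok) {
    if (tok %in% names(panel$accessory)) {
      b_gene(b, mutate_sequence(panel$accessory[[tok]], identity),
             sprintf("%s domain protein", tok), family = tok)
    } else if (tok %in% names(panel$other)) {
      b_gene(b, mutate_sequence(panel$other[[tok]], identity),
             sprintf("conserved protein %s", tok))
    } else stop_bad("unknown accessory/pool token %s", tok)
  }
  for (tok in accessory_before) emit_acc(tok)
  first_core <- NULL; last_core <- NULL; contig0 <- b$contig_id
  truncated <- "none"
  kept <- fams
  if (!is.null(truncate_after)) kept <- setdiff(kept, lost)
  for (fi in seq_along(kept)) {
    fam <- kept[[fi]]
    seq <- if (fam == "tssB") mutate_sequence(sheath_base$tssB, identity)
    else if (fam == "tssC") mutate_sequence(sheath_base$tssC, identity)
    else mutate_sequence(panel$core[[fam]], identity)
    gid <- b_gene(b, seq, sprintf("type VI secretion system protein %s", fam),
                  family = fam,
                  domains = sheath_domains_for(fam, nchar(seq)))
    note(gid, TRUE)
    if (fam == "tssB") { sheath_genes$tssB <- gid; tssB_seq_local <- seq }
    if (fam == "tssC") sheath_genes$tssC <- gid
    if (is.null(first_core)) first_core <- fam
    last_core <- fam
    if (fam == "tssC" && sheath_pattern == "fusion") {
      fseq <- compose_tsscl(tssB_seq_local, seq, fusion_identities)
      fgid <- b_gene(b, fseq, "type VI secretion system protein TssC",
                     family = "tssC",
                     domains = sheath_domains_for("tssC", nchar(fseq)))
      note(fgid, TRUE)
      sheath_genes$tssC_L <- fgid
    }
    if (fam == "tssC" && sheath_pattern == "duplication") {
      dseq <- mutate_sequence(seq, dup_identity)
      dgid <- b_gene(b, dseq, "type VI secretion system protein TssC",
                     family = "tssC",
                     domains = sheath_domains_for("tssC", nchar(dseq)))
      note(dgid, TRUE)
      sheath_genes$tssC_dup <- dgid
    }
    if (fam %in% names(accessory_inside)) {
      for (tok in accessory_inside[names(accessory_inside) == fam]) {
        note(emit_acc(tok), FALSE)
      }
    }
    if (fam %in% names(spacers)) {
      for (tok in spacers[names(spacers) == fam]) {
        note(b_gene(b, mutate_sequence(panel$spacer[[tok]], identity),
                    sprintf("conserved hypothetical protein %s", tok)),
             FALSE)
      }
    }
    if (!is.null(truncate_after) && fam == truncate_after) {
      truncated <- "right"
      b_contig(b, next_contig_id)
      break
    }
    if (fi < length(kept)) {
      ng <- if (!is.null(gaps) && fam %in% names(gaps)) gaps[[fam]]
      else if (!is.null(gaps)) 0L else gap_fun()
      if (ng > 0) {
        for (d in seq_len(ng)) {
          note(b_gene(b, random_protein(sample(80:150, 1)),
                      "hypothetical protein"), FALSE)
        }
      }
    }
  }
  for (tok in accessory_after) emit_acc(tok)
  # truth gene span: first to last core gene, intervening genes included
  core_kept <- if (is.null(truncate_after)) kept else
    kept[seq_len(match(truncate_after, kept))]
  first <- which(planted_is_core)[[1]]
  last <- which(planted_is_core)[[sum(planted_is_core)]]
  list(contig_id = contig0,
       gene_ids = planted[first:last],
       core_present = sort(unique(core_kept)),
       subtype = subtype, truncated = truncated,
       pattern = sheath_pattern,
       sheath_genes = sheath_genes,
       fusion_identities = if (sheath_pattern == "fusion") fusion_identities else NULL)
}

# ---- configuration and full set generation --------------------------------

#' Configuration for the synthetic genome set
#'
#' Defaults emulate the study panel: 34 light-organ-symbiont-style genomes
#' whose island genotypes follow the five archetype proportions
#' 52.9/2.9/11.8/11.7/20.6% (the third class split across two archetypes),
#' plus 6 roseobacter-style genomes (4 with a TssC_L fusion, 2 with a
#' duplicated tssC).
#'
#' @param n_genomes Number of island-panel genomes (default 34).
#' @param genotype_proportions Proportions of the 5 island archetypes
#'   (must sum to 1).
#' @param n_roseobacter Roseobacter-style genomes (default 6).
#' @param n_fusion How many roseobacter genomes carry TssC_L (default 4).
#' @param target_identity Mutation identity of planted genes to their
#'   family base (default 0.92).
#' @param t6ss1_divergence,t6ss2_divergence Identity of the per-set
#'   T6SS1/T6SS2 sheath bases to the subtype-1 reference (two clades).
#' @param roseo_divergence Identity of the roseobacter sheath base to the
#'   subtype-3 reference.
#' @param fusion_identities Fused VipA/VipA/VipB domain identities.
#' @param dup_identity Duplicated-tssC identity.
#' @param effector_identity Identity of planted effector homologs.
#' @param decoy_genes Decoy genes per contig flank (default 10).
#' @param gap_fun Intervening-gene-count distribution within clusters.
#' @param intergenic_bp Intergenic spacing (default 150).
#' @param seed Mandatory run seed.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_genomes = 34L,
                         genotype_proportions = c(0.529, 0.029, 0.118, 0.117, 0.206),
                         n_roseobacter = 6L, n_fusion = 4L,
                         target_identity = 0.92,
                         t6ss1_divergence = 0.80, t6ss2_divergence = 0.72,
                         roseo_divergence = 0.80,
                         fusion_identities = c(0.86, 0.26, 0.31),
                         dup_identity = 0.35,
                         effector_identity = 0.60,
                         decoy_genes = 10L,
                         gap_fun = function() sample(0:2, 1),
                         intergenic_bp = 150L,
                         seed) {
  if (missing(seed)) stop_bad("synth_config requires an explicit seed")
  # printed percentage sets often total 99.9 or 100.1; allow slight
  # rounding slack and normalise downstream
  if (abs(sum(genotype_proportions) - 1) > 0.005) {
    stop_bad("genotype proportions must sum to 1")
  }
  if (length(genotype_proportions) != 5) {
    stop_bad("exactly 5 genotype proportions required")
  }
  idents <- c(target_identity, fusion_identities, dup_identity,
              effector_identity, t6ss1_divergence, t6ss2_divergence,
              roseo_divergence)
  if (any(idents <= 0 | idents > 1)) stop_bad("identities must lie in (0, 1]")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate the synthetic annotated genome set with ground truth
#'
#' Writes, per genome, GFF3 + genomic FASTA + protein FASTA and a GenBank
#' twin; set-level, an HMMER-style family hit table, the effector database
#' with planted homologs, labelled subtype reference sheaths, a replicon
#' map, and the truth JSON. Fully deterministic given the config seed.
#'
#' @param config A `synth_config`.
#' @param out_dir Output directory.
#' @return Invisibly, list with `dir`, `genome_ids`, `truth`.
#' @export
generate_genome_set <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- family_reference_panel()
  with_seed(config$seed, {
    counts <- apportion_largest_remainder(config$n_genomes,
                                          config$genotype_proportions)
    genotype_of <- sample(rep(seq_len(5), counts))
    # per-set sheath bases: two subtype-1 clades (T6SS1, T6SS2), one
    # subtype-3 roseobacter clade
    base1 <- list(tssB = mutate_sequence(panel$subtype_refs[["1"]]$tssB,
                                         config$t6ss1_divergence),
                  tssC = mutate_sequence(panel$subtype_refs[["1"]]$tssC,
                                         config$t6ss1_divergence))
    base2 <- list(tssB = mutate_sequence(panel$subtype_refs[["1"]]$tssB,
                                         config$t6ss2_divergence),
                  tssC = mutate_sequence(panel$subtype_refs[["1"]]$tssC,
                                         config$t6ss2_divergence))
    base3 <- list(tssB = mutate_sequence(panel$subtype_refs[["3"]]$tssB,
                                         config$roseo_divergence),
                  tssC = mutate_sequence(panel$subtype_refs[["3"]]$tssC,
                                         config$roseo_divergence))
    truth_genomes <- list(); all_hits <- list(); genome_ids <- character(0)
    replicons <- list()

    write_genome <- function(genome) {
      gid <- genome$genome_id
      write_gff_genome(genome,
                       file.path(out_dir, paste0(gid, ".gff")),
                       file.path(out_dir, paste0(gid, ".fna")),
                       file.path(out_dir, paste0(gid, ".faa")))
      write_genbank(genome, file.path(out_dir, paste0(gid, ".gbk")))
    }

    for (i in seq_len(config$n_genomes)) {
      gid <- sprintf("VF%02d", i)
      genome_ids <- c(genome_ids, gid)
      gt <- genotype_of[[i]]
      b <- new_builder(gid, config$intergenic_bp)
      clusters <- list()

      # chromosome 1: backbone decoys, a planted effector homolog, T6SS1
      b_contig(b, paste0(gid, "_chr1"))
      b_decoys(b, config$decoy_genes)
      eff_tok <- names(panel$effectors)[((i - 1) %% 5) + 1]
      eff_gene <- b_gene(b, mutate_sequence(panel$effectors[[eff_tok]],
                                            config$effector_identity),
                         "putative secreted effector protein")
      clusters$T6SS1 <- plant_cluster(
        b, panel, base1, subtype = "1",
        missing = c("tssD", "tssI"),
        accessory_inside = c(tssL = "PP2C", tssL = "Pkinase", tssL = "FHA"),
        gap_fun = config$gap_fun,
        identity = config$target_identity)
      b_decoys(b, config$decoy_genes)

      # chromosome 2: island between manA and tRNA-Gly
      b_contig(b, paste0(gid, "_chr2"))
      b_decoys(b, config$decoy_genes)
      manA_gid <- b_gene(b, mutate_sequence(panel$manA, config$target_identity),
                         "mannose-6-phosphate isomerase manA")
      manA_start <- b$genes[[length(b$genes)]]$start
      island_first <- manA_gid
      island_status <- "resolved"
      if (gt %in% c(1, 2)) {
        for (tok in paste0("otherA", 1:4)) {
          b_gene(b, mutate_sequence(panel$other[[tok]], config$target_identity),
                 sprintf("conserved protein %s", tok))
        }
        cl <- plant_cluster(
          b, panel, base2, subtype = "1",
          accessory_before = "DUF4150",
          accessory_inside = c(tssL = "FHA", tssL = "Pkinase", tssL = "tasR"),
          accessory_after = if (gt == 1) c("tasL", "vasH") else character(0),
          spacers = c(tssC = "spc1", tssI = "spc2"),
          gaps = integer(0),  # fixed template, no random gaps inside the island
          identity = config$target_identity,
          truncate_after = if (gt == 2) "tssJ" else NULL,
          next_contig_id = paste0(gid, "_chr2b"),
          lost = if (gt == 2) c("tssK", "tssL", "tssM") else character(0))
        clusters$T6SS2 <- cl
        if (gt == 2) {
          island_status <- "concatenated_one_break"
          for (tok in c("tasL", "vasH")) {
            b_gene(b, mutate_sequence(panel$accessory[[tok]],
                                      config$target_identity),
                   sprintf("%s domain protein", tok), family = tok)
          }
        }
        for (tok in paste0("otherA", 5:8)) {
          b_gene(b, mutate_sequence(panel$other[[tok]], config$target_identity),
                 sprintf("conserved protein %s", tok))
        }
        trna <- b_gene(b, "", "tRNA-Gly", kind = "tRNA")
      } else if (gt %in% c(3, 4)) {
        pool <- if (gt == 3) paste0("otherB", 1:8) else paste0("otherC", 1:8)
        for (tok in pool) {
          b_gene(b, mutate_sequence(panel$other[[tok]], config$target_identity),
                 sprintf("conserved protein %s", tok))
        }
        # pad the flank spacing so the gene-bearing T6SS2-less genotypes
        # realise mid-range island sizes (20 / 25 kbp flank-inclusive)
        span <- if (gt == 3) 20000L else 25000L
        trna <- b_gene(b, "", "tRNA-Gly", kind = "tRNA",
                       at = manA_start + span - 76L)
      } else {
        for (tok in c("otherE1", "otherE2")) {
          b_gene(b, mutate_sequence(panel$other[[tok]], config$target_identity),
                 sprintf("conserved protein %s", tok))
        }
        # near-empty genotype realises the lower bound of the island size
        # range: flank-inclusive span of exactly 11.2 kbp
        trna <- b_gene(b, "", "tRNA-Gly", kind = "tRNA",
                       at = manA_start + 11200L - 76L)
      }
      b_decoys(b, config$decoy_genes)

      built <- b_finish(b, source = "host-associated",
                        taxon_label = "Vibrio fischeri (synthetic)")
      write_genome(built$genome)
      all_hits[[gid]] <- built$hits
      replicons[[gid]] <- data.frame(
        contig_id = built$genome$contigs$contig_id,
        chromosome = ifelse(grepl("_chr1$", built$genome$contigs$contig_id),
                            1L, 2L),
        stringsAsFactors = FALSE)
      truth_genomes[[gid]] <- list(
        style = "fischeri", genotype = gt,
        island_status = island_status,
        clusters = clusters,
        effector_genes = eff_gene,
        repertoires = stats::setNames(
          lapply(clusters, function(x) x$pattern), names(clusters)))
    }

    for (j in seq_len(config$n_roseobacter)) {
      gid <- sprintf("RB%02d", j)
      genome_ids <- c(genome_ids, gid)
      pat <- if (j <= config$n_fusion) "fusion" else "duplication"
      b <- new_builder(gid, config$intergenic_bp)
      b_contig(b, paste0(gid, "_c1"))
      b_decoys(b, config$decoy_genes)
      eff_tok <- names(panel$effectors)[((j - 1) %% 5) + 1]
      eff_gene <- b_gene(b, mutate_sequence(panel$effectors[[eff_tok]],
                                            config$effector_identity),
                         "putative secreted effector protein")
      cl <- plant_cluster(
        b, panel, base3, subtype = "3",
        missing = "tssJ",
        accessory_inside = c(tssI = "PAAR", tssI = "FHA", tssI = "impE"),
        gap_fun = config$gap_fun,
        identity = config$target_identity,
        sheath_pattern = pat,
        fusion_identities = config$fusion_identities,
        dup_identity = config$dup_identity)
      b_decoys(b, config$decoy_genes)
      built <- b_finish(b, source = "host-associated",
                        taxon_label = "roseobacter ANG symbiont (synthetic)")
      write_genome(built$genome)
      all_hits[[gid]] <- built$hits
      truth_genomes[[gid]] <- list(
        style = "roseobacter", genotype = NA,
        island_status = "unresolved",
        clusters = list(T6SS_roseo = cl),
        effector_genes = eff_gene,
        repertoires = list(T6SS_roseo = pat))
    }

    # set-level files
    hits <- do.call(rbind, unname(all_hits))
    writeLines(domtbl_lines(hits), file.path(out_dir, "hits.domtbl"))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(panel$effectors),
      file.path(out_dir, "effector_db.faa"), width = 70)
    refs <- Biostrings::AAStringSet(vapply(panel$subtype_refs, function(r)
      paste0(r$tssB, r$tssC), ""))
    names(refs) <- sprintf("ref_s%s subtype=%s",
                           names(panel$subtype_refs), names(panel$subtype_refs))
    Biostrings::writeXStringSet(refs,
                                file.path(out_dir, "reference_sheaths.faa"),
                                width = 70)
    write_tsv_plain(do.call(rbind, unname(replicons)),
                    file.path(out_dir, "replicons.tsv"))

    # expected distinct island families (CDS families by planted token,
    # plus the tRNA flank family)
    island_tokens <- c("manA", paste0("otherA", 1:8), "DUF4150",
                       t6ss_core_families(), "FHA", "Pkinase", "tasR",
                       "tasL", "vasH", "spc1", "spc2",
                       paste0("otherB", 1:8), paste0("otherC", 1:8),
                       "otherE1", "otherE2")
    truth <- list(
      seed = config$seed,
      n_genomes = config$n_genomes,
      n_roseobacter = config$n_roseobacter,
      genotype_counts = counts,
      island_family_count = length(unique(island_tokens)) + 1L,
      genomes = truth_genomes)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    invisible(list(dir = out_dir, genome_ids = genome_ids, truth = truth))
  })
}

# domtblout lines for a set-level hit table (lengths not tracked per gene
# here; the loader does not use the tlen column).
domtbl_lines <- function(hits) {
  hdr <- "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"
  if (!nrow(hits)) return(hdr)
  c(hdr, sprintf(
    "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.99 -",
    hits$gene_id, hits$ali_end - hits$ali_start, hits$family,
    hits$ali_end - hits$ali_start, hits$evalue, hits$score, hits$evalue,
    hits$evalue, hits$score, hits$ali_end - hits$ali_start,
    hits$ali_start + 1L, hits$ali_end, hits$ali_start + 1L, hits$ali_end))
}
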