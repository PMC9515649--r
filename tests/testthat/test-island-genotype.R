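# Island extraction between the manA / tRNA-Gly flanks, homolog-family
# presence/absence matrices, genotype clustering and archetype labelling.

island_genome <- function(genome_id = "I1", n_between = 2,
                          between_prots = NULL, trna_at = NULL,
                          with_manA = TRUE) {
  fams <- c(rep("x", 2), if (with_manA) "manA" else "x",
            rep("x", n_between), "trna", rep("x", 2))
  n <- length(fams)
  prots <- character(n)
  k <- 0
  for (i in seq_len(n)) {
    prots[i] <- if (fams[i] == "trna") "" else
      if (fams[i] == "x" || !with_manA) random_aa(100) else random_aa(390)
  }
  if (!is.null(between_prots)) {
    idx <- which(fams == "x")
    between_idx <- seq(which(fams %in% c("manA"))[1] + 1,
                       which(fams == "trna") - 1)
    prots[between_idx] <- between_prots
  }
  widths <- ifelse(fams == "trna", 76L, 1000L)
  starts <- integer(n); pos <- 0L
  for (i in seq_len(n)) {
    if (!is.null(trna_at) && fams[i] == "trna") pos <- as.integer(trna_at)
    starts[i] <- pos
    pos <- pos + widths[i] + 200L
  }
  genes <- data.frame(
    gene_id = sprintf("%s_%03d", genome_id, seq_len(n)),
    contig_id = "c1",
    start = starts,
    end = starts + widths,
    strand = "+",
    feature_kind = ifelse(fams == "trna", "tRNA", "CDS"),
    product = ifelse(fams == "trna", "tRNA-Gly",
                     ifelse(fams == "manA", "mannose-6-phosphate isomerase manA",
                            "hypothetical protein")),
    protein_seq = ifelse(fams == "trna", "", prots),
    stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = "c1", length = max(genes$end) + 2000L,
                        stringsAsFactors = FALSE)
  annotated_genome(genome_id, contigs, genes)
}

test_that("flanks 11.2 kbp apart with two intervening genes resolve at 11.2 kbp", {
  set.seed(41)
  manA_start <- 2 * 1200L
  g <- island_genome(n_between = 2, trna_at = manA_start + 11200L - 76L)
  isl <- extract_island(g)
  expect_equal(isl$status, "resolved")
  expect_equal(length(isl$gene_ids), 4)   # manA + 2 + tRNA
  expect_equal(isl$length_bp, 11200L)
})

test_that("a missing flank leaves the island unresolved with empty genes", {
  set.seed(42)
  g <- island_genome(with_manA = FALSE)
  isl <- extract_island(g)
  expect_equal(isl$status, "unresolved")
  expect_equal(length(isl$gene_ids), 0)
  expect_match(isl$reason, "manA")
})

test_that("flanks on two contigs joined at one break concatenate in flank order", {
  set.seed(43)
  # contig A: backbone, manA, two island genes to the right edge
  # contig B: island gene from the left edge, tRNA-Gly, backbone
  ga <- data.frame(
    gene_id = sprintf("S_%03d", 1:4), contig_id = "cA",
    start = (0:3) * 1200L, end = (0:3) * 1200L + 1000L,
    strand = "+", feature_kind = "CDS",
    product = c("hypothetical protein", "mannose-6-phosphate isomerase manA",
                "island protein 1", "island protein 2"),
    protein_seq = vapply(1:4, function(i) random_aa(100), ""),
    stringsAsFactors = FALSE)
  gb <- data.frame(
    gene_id = sprintf("S_%03d", 5:7), contig_id = "cB",
    start = (0:2) * 1200L, end = (0:2) * 1200L + c(1000L, 76L, 1000L),
    strand = "+", feature_kind = c("CDS", "tRNA", "CDS"),
    product = c("island protein 3", "tRNA-Gly", "hypothetical protein"),
    protein_seq = c(random_aa(100), "", random_aa(100)),
    stringsAsFactors = FALSE)
  g <- annotated_genome("S", data.frame(contig_id = c("cA", "cB"),
                                        length = c(5000L, 4000L)),
                        rbind(ga, gb))
  isl <- extract_island(g)
  expect_equal(isl$status, "concatenated_one_break")
  expect_equal(isl$gene_ids,
               c("S_002", "S_003", "S_004", "S_005", "S_006"))
  expect_equal(isl$flank_a_gene, "S_002")
  expect_equal(isl$flank_b_gene, "S_006")
})

test_that("shared proteins collapse to one family, 50% identity stays apart", {
  set.seed(44)
  shared <- random_aa(200)
  half <- mutate_sequence(shared, 0.5)
  g1 <- island_genome("I1", n_between = 2, between_prots = c(shared, random_aa(150)))
  g2 <- island_genome("I2", n_between = 2, between_prots = c(shared, half))
  islands <- list(extract_island(g1), extract_island(g2))
  genomes <- list(I1 = g1, I2 = g2)
  pm <- build_presence_matrix(islands, genomes)
  shared_fam <- pm$families$family[pm$families$protein_seq == shared |
                                     pm$families$gene_id %in%
                                     c("I1_004", "I2_004")]
  # the shared protein's family is present in both genomes
  fam_shared <- pm$families$family[pm$families$gene_id == "I1_004"]
  expect_equal(fam_shared, pm$families$family[pm$families$gene_id == "I2_004"])
  expect_equal(unname(pm$matrix[, fam_shared]), c(1L, 1L))
  # the 50% mutant founds its own family
  fam_half <- pm$families$family[pm$families$gene_id == "I2_005"]
  expect_false(fam_half == fam_shared)
  # partition property: every island gene in exactly one family
  for (isl in islands) {
    fams <- pm$families[pm$families$genome_id == isl$genome_id, ]
    expect_setequal(fams$gene_id, isl$gene_ids)
    expect_equal(anyDuplicated(fams$gene_id), 0)
  }
  expect_error(build_presence_matrix(islands[1], genomes), "at least 2")
})

test_that("two orthogonal presence blocks cluster into k = 2", {
  m <- rbind(matrix(rep(c(1L, 0L), c(5, 5)), 4, 10, byrow = TRUE),
             matrix(rep(c(0L, 1L), c(5, 5)), 4, 10, byrow = TRUE))
  dimnames(m) <- list(paste0("g", 1:8), paste0("f", 1:10))
  ct <- cluster_genotypes(m)
  expect_equal(attr(ct, "k"), 2L)
  expect_equal(length(unique(ct$genotype[1:4])), 1)
  expect_equal(length(unique(ct$genotype[5:8])), 1)
  expect_false(ct$genotype[1] == ct$genotype[5])
})

test_that("row permutation leaves the partition unchanged up to relabeling", {
  set.seed(46)
  m <- rbind(matrix(rep(c(1L, 0L, 0L), c(4, 4, 4)), 5, 12, byrow = TRUE),
             matrix(rep(c(0L, 1L, 0L), c(4, 4, 4)), 3, 12, byrow = TRUE),
             matrix(rep(c(0L, 0L, 1L), c(4, 4, 4)), 4, 12, byrow = TRUE))
  dimnames(m) <- list(sprintf("g%02d", 1:12), paste0("f", 1:12))
  a <- cluster_genotypes(m)
  b <- cluster_genotypes(m[sample(nrow(m)), ])
  merged <- merge(a, b, by = "genome_id")
  expect_equal(mclust::adjustedRandIndex(merged$genotype.x, merged$genotype.y), 1)
  # with the deterministic size-based relabeling the labels agree exactly
  expect_equal(merged$genotype.x, merged$genotype.y)
})

test_that("identical rows collapse to a single genotype with a warning", {
  m <- matrix(1L, 4, 6, dimnames = list(paste0("g", 1:4), paste0("f", 1:6)))
  expect_warning(ct <- cluster_genotypes(m), "identical")
  expect_equal(unique(ct$genotype), 1L)
})

test_that("archetype rules label complete, gene-bearing and near-empty islands", {
  set.seed(47)
  # three synthetic islands: one embedding a complete 13-core cluster, one
  # with many non-flank genes and no cluster, one with nothing but flanks
  cores <- t6ss_core_families()
  g_full <- island_genome("A1", n_between = 13,
                          between_prots = vapply(cores, function(f)
                            random_aa(150), ""))
  fmap <- toy_family_map(g_full, c("x", "x", "x", cores, "x", "x", "x"))
  cl_full <- scan_genome(g_full, fmap)
  g_genes <- island_genome("A2", n_between = 10)
  g_empty <- island_genome("A3", n_between = 0)
  islands <- list(A1 = extract_island(g_full), A2 = extract_island(g_genes),
                  A3 = extract_island(g_empty))
  genotypes <- data.frame(genome_id = c("A1", "A2", "A3"),
                          genotype = c(1L, 2L, 3L), stringsAsFactors = FALSE)
  arch <- label_archetype(genotypes, islands, cl_full)
  expect_equal(arch$archetype,
               c("complete_T6SS2_plus_genes", "no_T6SS2_with_genes",
                 "near_empty"))
  expect_false(any(arch$mixed))
})
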