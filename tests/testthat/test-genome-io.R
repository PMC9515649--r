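# Genome model and format round-trips.

test_that("GFF 1-based inclusive coordinates become 0-based half-open", {
  d <- tempfile(); dir.create(d)
  writeLines(c("##gff-version 3",
               "##sequence-region c1 1 5000",
               "c1\tsrc\tCDS\t11\t40\t.\t+\t0\tID=g1;product=demo",
               "c1\tsrc\tCDS\t501\t560\t.\t-\t0\tID=g3;product=late",
               "c1\tsrc\tCDS\t101\t190\t.\t+\t0\tID=g2;product=mid"),
             file.path(d, "t.gff"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(c1 = paste(rep("ACGT", 1250), collapse = ""))),
    file.path(d, "t.fna"))
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(c(g1 = "MKTAYIAKQR", g2 = "MNPQRSTVWYACDEFGHIKLMNPQRSTVW",
                              g3 = "MAAAAAAAAAAAAAAAAAAK")),
    file.path(d, "t.faa"))
  g <- read_gff_genome(file.path(d, "t.gff"), file.path(d, "t.fna"),
                       file.path(d, "t.faa"))
  expect_equal(g$genes$start[1], 10)
  expect_equal(g$genes$end[1], 40)
  # genes sorted by start regardless of file order
  expect_equal(g$genes$gene_id, c("g1", "g2", "g3"))
  # missing protein cross-reference is a hard error naming the gene
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t11\t40\t.\t+\t0\tID=gX;product=demo"),
             file.path(d, "bad.gff"))
  expect_error(read_gff_genome(file.path(d, "bad.gff"), file.path(d, "t.fna"),
                               file.path(d, "t.faa")), "gX")
})

test_that("coordinate conversion preserves length in both directions", {
  g <- toy_genome(c("tssA", "x"))
  d <- tempfile(); dir.create(d)
  paths <- file.path(d, c("g.gff", "g.fna", "g.faa"))
  g$contig_seqs <- stats::setNames(
    paste(rep("ACGT", ceiling(g$contigs$length / 4)), collapse = ""),
    g$contigs$contig_id)
  g$contig_seqs <- substr(g$contig_seqs, 1, g$contigs$length)
  write_gff_genome(g, paths[1], paths[2], paths[3])
  gff <- read.delim(paths[1], header = FALSE, comment.char = "#")
  expect_equal(gff$V5 - gff$V4 + 1, g$genes$end - g$genes$start)
})

test_that("generated fixtures round-trip read -> write -> read identically", {
  set <- default_set()
  dir <- .t6_cache$set_dir
  g1 <- read_gff_genome(file.path(dir, "VF03.gff"), file.path(dir, "VF03.fna"),
                        file.path(dir, "VF03.faa"))
  d <- tempfile(); dir.create(d)
  write_gff_genome(g1, file.path(d, "r.gff"), file.path(d, "r.fna"),
                   file.path(d, "r.faa"))
  g2 <- read_gff_genome(file.path(d, "r.gff"), file.path(d, "r.fna"),
                        file.path(d, "r.faa"), genome_id = g1$genome_id)
  expect_equal(g2$genes, g1$genes)
  expect_equal(g2$contigs, g1$contigs)
  expect_equal(g2$contig_seqs, g1$contig_seqs)
})

test_that("GenBank single- and multi-record files parse to the model", {
  d <- tempfile(); dir.create(d)
  g <- toy_genome(c("tssA", "x"))
  g$contig_seqs <- stats::setNames(
    substr(paste(rep("ACGT", 1000), collapse = ""), 1, g$contigs$length),
    g$contigs$contig_id)
  write_genbank(g, file.path(d, "one.gbk"))
  back <- read_genbank(file.path(d, "one.gbk"), genome_id = "G")
  expect_equal(nrow(back$contigs), 1)
  expect_equal(nrow(back$genes), 2)
  expect_equal(back$genes[, c("gene_id", "start", "end", "protein_seq")],
               g$genes[, c("gene_id", "start", "end", "protein_seq")])

  # multi-record: one contig per record
  two <- g
  two$contigs <- data.frame(contig_id = c("c1", "c2"),
                            length = c(g$contigs$length, 4000L),
                            stringsAsFactors = FALSE)
  extra <- g$genes[1, ]
  extra$gene_id <- "G_999"; extra$contig_id <- "c2"
  two$genes <- rbind(g$genes, extra)
  two$contig_seqs <- c(two$contig_seqs,
                       c2 = substr(paste(rep("ACGT", 1000), collapse = ""), 1, 4000))
  two <- annotated_genome("G2", two$contigs, two$genes,
                          contig_seqs = two$contig_seqs)
  write_genbank(two, file.path(d, "two.gbk"))
  back2 <- read_genbank(file.path(d, "two.gbk"))
  expect_equal(nrow(back2$contigs), 2)
  expect_equal(sum(back2$genes$contig_id == "c2"), 1)
})

test_that("a CDS without a translation is kept empty with a warning", {
  d <- tempfile(); dir.create(d)
  writeLines(c("LOCUS       c1 900 bp    DNA     linear   BCT",
               "DEFINITION  test.",
               "FEATURES             Location/Qualifiers",
               "     CDS             1..99",
               '                     /locus_tag="g1"',
               '                     /product="no translation here"',
               "ORIGIN",
               sprintf("%9d %s", 1, paste(rep("acgtacgtac", 6), collapse = " ")),
               "//"), file.path(d, "nt.gbk"))
  expect_warning(g <- read_genbank(file.path(d, "nt.gbk")), "translation")
  expect_equal(g$genes$protein_seq, "")
  expect_equal(g$genes$feature_kind, "CDS")
})

test_that("the GenBank twin parses to the same model as its GFF sibling", {
  set <- default_set()
  dir <- .t6_cache$set_dir
  for (gid in c("VF01", "RB01")) {
    from_gff <- read_gff_genome(file.path(dir, paste0(gid, ".gff")),
                                file.path(dir, paste0(gid, ".fna")),
                                file.path(dir, paste0(gid, ".faa")))
    from_gbk <- read_genbank(file.path(dir, paste0(gid, ".gbk")),
                             genome_id = gid)
    expect_equal(from_gbk$genes, from_gff$genes)
    expect_equal(from_gbk$contigs, from_gff$contigs)
  }
})

test_that("the genome model enforces its invariants", {
  g <- toy_genome(c("tssA", "x"))
  bad <- g$genes; bad$start[1] <- bad$end[1]
  expect_error(annotated_genome("B", g$contigs, bad), "start >= end")
  dup <- rbind(g$genes, g$genes[1, ])
  expect_error(annotated_genome("B", g$contigs, dup), "duplicate gene")
  past <- g$genes; past$end[2] <- g$contigs$length + 10L
  expect_error(annotated_genome("B", g$contigs, past), "past contig end")
  aa_bad <- g$genes; aa_bad$protein_seq[1] <- "MKT1"
  expect_error(annotated_genome("B", g$contigs, aa_bad), "amino acids")
})

test_that("report writing emits header-only tables for empty results and counts rows", {
  d <- tempfile()
  files <- write_reports(list(config = list(seed = 1)), d)
  cl <- read.delim(file.path(d, "clusters.tsv"))
  expect_equal(nrow(cl), 0)
  expect_true(all(c("cluster_id", "core_present", "truncated") %in% names(cl)))
  gt <- read.delim(file.path(d, "genotypes.tsv"))
  expect_equal(nrow(gt), 0)

  # populated: 2 genomes, 3 clusters -> 3 cluster rows, 2 genotype rows
  cl3 <- rbind(scan_labels(c("tssA", "tssB", "tssC", "tssK", rep("x", 11),
                             "tssA", "tssB", "tssC", "tssL")),
               scan_labels(c("tssA", "tssB", "tssC", "tssM")))
  cl3$genome_id <- c("g1", "g1", "g2")
  res <- list(clusters = cl3,
              genotypes = data.frame(genome_id = c("g1", "g2"),
                                     genotype = c(1L, 2L),
                                     archetype = c("near_empty", "near_empty"),
                                     island_status = "resolved",
                                     island_length_bp = c(11200L, 11200L)),
              config = list(seed = 1, min_core = 4))
  d2 <- tempfile()
  write_reports(res, d2)
  expect_equal(nrow(read.delim(file.path(d2, "clusters.tsv"))), 3)
  expect_equal(nrow(read.delim(file.path(d2, "genotypes.tsv"))), 2)
  # manifest echoes the config
  man <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_equal(man$config$seed, 1)
  expect_equal(man$config$min_core, 4)
  expect_equal(man$tool, "t6sscan")
})
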