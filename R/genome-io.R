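# Canonical genome data model and readers/writers for the formats the
# pipeline touches: GFF3 (Prokka dialect) + genomic/protein FASTA, GenBank
# flat files, and the TSV/JSON report set.
#
# Coordinates are stored 0-based half-open internally; GFF and GenBank are
# 1-based inclusive and are converted on the way in and out, so
# length = end - start holds everywhere internally.

GENE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
               "feature_kind", "product", "protein_seq")

#' Construct an annotated genome
#'
#' The in-memory genome model used throughout the pipeline: an ordered gene
#' table over one or more contigs. Genes are sorted within contigs by start,
#' ties broken by end then gene_id.
#'
#' @param genome_id Genome identifier.
#' @param contigs `data.frame` with columns `contig_id`, `length` (bp).
#' @param genes `data.frame` with columns `gene_id`, `contig_id`, `start`,
#'   `end` (0-based half-open), `strand` (`+`/`-`), `feature_kind`
#'   (`CDS`/`tRNA`/`other`), `product`, `protein_seq` (may be `""` for RNA
#'   features).
#' @param source Isolation source: `host-associated`, `environmental`, or
#'   `unknown`.
#' @param taxon_label Free-text taxon label.
#' @param contig_seqs Optional named character of contig nucleotide
#'   sequences.
#' @return An `annotated_genome` object.
#' @export
annotated_genome <- function(genome_id, contigs, genes,
                             source = "unknown", taxon_label = "",
                             contig_seqs = NULL) {
  source <- match.arg(source, c("host-associated", "environmental", "unknown"))
  stopifnot(all(c("contig_id", "length") %in% names(contigs)),
            all(GENE_COLS %in% names(genes)))
  if (anyDuplicated(contigs$contig_id)) {
    stop_bad("duplicate contig ids in genome %s", genome_id)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop_bad("duplicate gene ids in genome %s", genome_id)
  }
  if (nrow(genes)) {
    if (any(genes$start >= genes$end)) {
      stop_bad("gene with start >= end in genome %s", genome_id)
    }
    bad <- setdiff(genes$contig_id, contigs$contig_id)
    if (length(bad)) stop_bad("gene on unknown contig %s", bad[[1]])
    clen <- stats::setNames(contigs$length, contigs$contig_id)
    if (any(genes$end > clen[genes$contig_id])) {
      stop_bad("gene extends past contig end in genome %s", genome_id)
    }
    check_protein(genes$protein_seq, sprintf("genome %s proteins", genome_id))
    ord <- order(match(genes$contig_id, contigs$contig_id),
                 genes$start, genes$end, genes$gene_id)
    genes <- genes[ord, GENE_COLS]
    rownames(genes) <- NULL
  } else {
    genes <- genes[, GENE_COLS]
  }
  structure(list(genome_id = genome_id, contigs = contigs, genes = genes,
                 source = source, taxon_label = taxon_label,
                 contig_seqs = contig_seqs),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d contig(s), %d gene(s), source=%s\n",
              x$genome_id, nrow(x$contigs), nrow(x$genes), x$source))
  invisible(x)
}

#' Genes of one contig, in positional order
#' @param genome An `annotated_genome`.
#' @param contig_id Contig identifier.
#' @return The gene `data.frame` subset for that contig.
#' @export
contig_genes <- function(genome, contig_id) {
  g <- genome$genes[genome$genes$contig_id == contig_id, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Read a Prokka-style GFF3 genome with its FASTA companions
#'
#' @param gff_path GFF3 file with CDS/tRNA features carrying `ID` (and
#'   usually `product`) attributes.
#' @param genome_fasta_path Nucleotide FASTA of the contigs.
#' @param protein_fasta_path Protein FASTA whose ids match the GFF `ID`
#'   attributes.
#' @param genome_id Genome id (default: GFF filename stem).
#' @param source,taxon_label Metadata passed to [annotated_genome()].
#' @return An `annotated_genome`. CDS features lacking a protein sequence
#'   raise an error naming the gene; tRNA features are retained with an
#'   empty protein.
#' @export
read_gff_genome <- function(gff_path, genome_fasta_path, protein_fasta_path,
                            genome_id = NULL, source = "unknown",
                            taxon_label = "") {
  genome_id <- genome_id %||% sub("\\.gff3?$", "", basename(gff_path))
  gff <- as.data.frame(rtracklayer::readGFF(
    gff_path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "product")))
  keep <- gff$type %in% c("CDS", "tRNA")
  gff <- gff[keep, , drop = FALSE]
  if (nrow(gff) && any(is.na(gff$ID) | !nzchar(gff$ID))) {
    stop_bad("GFF feature without an ID attribute in %s", gff_path)
  }
  nt <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(nt) <- sub("\\s.*$", "", names(nt))
  aa <- Biostrings::readAAStringSet(protein_fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  prot <- rep("", nrow(gff))
  is_cds <- gff$type == "CDS"
  missing_prot <- is_cds & !(gff$ID %in% names(aa))
  if (any(missing_prot)) {
    stop_bad("CDS %s has no protein sequence in %s",
             gff$ID[missing_prot][[1]], protein_fasta_path)
  }
  prot[is_cds] <- as.character(aa[gff$ID[is_cds]])
  genes <- data.frame(
    gene_id = as.character(gff$ID),
    contig_id = as.character(gff$seqid),
    start = gff$start - 1L,      # 1-based inclusive -> 0-based half-open
    end = gff$end,
    strand = as.character(gff$strand),
    feature_kind = ifelse(gff$type == "CDS", "CDS", "tRNA"),
    product = ifelse(is.na(gff$product), "", as.character(gff$product)),
    protein_seq = prot,
    stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = names(nt), length = Biostrings::width(nt),
                        stringsAsFactors = FALSE)
  annotated_genome(genome_id, contigs, genes, source, taxon_label,
                   contig_seqs = stats::setNames(as.character(nt), names(nt)))
}

#' Write a genome back to GFF3 + FASTA
#'
#' Inverse of [read_gff_genome()]; coordinates are serialised 1-based
#' inclusive.
#'
#' @param genome An `annotated_genome` (must carry contig sequences).
#' @param gff_path,genome_fasta_path,protein_fasta_path Output paths.
#' @return Invisibly, the GFF path.
#' @export
write_gff_genome <- function(genome, gff_path, genome_fasta_path,
                             protein_fasta_path) {
  if (is.null(genome$contig_seqs)) {
    stop_bad("genome %s carries no contig sequences", genome$genome_id)
  }
  g <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d",
                     genome$contigs$contig_id, genome$contigs$length))
  if (nrow(g)) {
    attrs <- sprintf("ID=%s;product=%s", g$gene_id, g$product)
    lines <- c(lines, sprintf("%s\tt6sscan\t%s\t%d\t%d\t.\t%s\t0\t%s",
                              g$contig_id,
                              ifelse(g$feature_kind == "CDS", "CDS", "tRNA"),
                              g$start + 1L, g$end, g$strand, attrs))
  }
  writeLines(lines, gff_path)
  nt <- Biostrings::DNAStringSet(genome$contig_seqs)
  Biostrings::writeXStringSet(nt, genome_fasta_path, width = 70)
  cds <- g[g$feature_kind == "CDS", , drop = FALSE]
  aa <- Biostrings::AAStringSet(stats::setNames(cds$protein_seq, cds$gene_id))
  Biostrings::writeXStringSet(aa, protein_fasta_path, width = 70)
  invisible(gff_path)
}

#' Read a GenBank flat file
#'
#' Minimal parser for multi-record GenBank flat files with CDS features
#' carrying `/translation` qualifiers (one contig per record). A CDS without
#' a translation is retained with an empty protein and a warning.
#'
#' @param path GenBank flat file.
#' @param genome_id Genome id (default: filename stem).
#' @param source,taxon_label Metadata passed to [annotated_genome()].
#' @return An `annotated_genome`.
#' @export
read_genbank <- function(path, genome_id = NULL, source = "unknown",
                         taxon_label = "") {
  genome_id <- genome_id %||% sub("\\.(gbk?|gbff)$", "", basename(path))
  lines <- readLines(path)
  rec_start <- grep("^LOCUS", lines)
  if (!length(rec_start)) stop_bad("no LOCUS record in %s", path)
  rec_end <- c(rec_start[-1] - 1L, length(lines))
  contigs <- list(); genes <- list(); seqs <- character(0)
  for (r in seq_along(rec_start)) {
    rl <- lines[rec_start[r]:rec_end[r]]
    locus <- strsplit(trimws(rl[[1]]), "\\s+")[[1]]
    contig_id <- locus[[2]]
    clen <- as.integer(locus[[3]])
    feat0 <- grep("^FEATURES", rl)[1]
    orig0 <- grep("^ORIGIN", rl)[1]
    # sequence block
    seq <- ""
    if (!is.na(orig0)) {
      sl <- rl[(orig0 + 1):length(rl)]
      sl <- sl[!grepl("^//", sl)]
      seq <- toupper(gsub("[^a-zA-Z]", "", paste(sl, collapse = "")))
    }
    # feature block: feature keys start at column 6, qualifiers at 22
    fl <- rl[(feat0 + 1):(if (is.na(orig0)) length(rl) else orig0 - 1)]
    key_idx <- grep("^ {5}\\S", fl)
    gi <- 0L
    for (k in seq_along(key_idx)) {
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(fl)
      key <- sub("^ {5}(\\S+).*$", "\\1", fl[from])
      if (!key %in% c("CDS", "tRNA")) next
      block <- paste(trimws(fl[from:to]), collapse = " ")
      loc <- sub(sprintf("^%s\\s+(\\S+).*$", key), "\\1", block)
      strand <- if (grepl("complement", loc)) "-" else "+"
      nums <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
      qual <- function(name) {
        m <- regmatches(block,
                        regexpr(sprintf('/%s="[^"]*"', name), block))
        if (!length(m)) return("")
        sub(sprintf('^/%s="', name), "", sub('"$', "", m))
      }
      gid <- qual("locus_tag")
      if (!nzchar(gid)) { gi <- gi + 1L; gid <- sprintf("%s_f%03d", contig_id, gi) }
      trans <- gsub("\\s", "", qual("translation"))
      if (key == "CDS" && !nzchar(trans)) {
        warning(sprintf("CDS %s has no /translation; protein left empty", gid),
                call. = FALSE)
      }
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, contig_id = contig_id,
        start = min(nums) - 1L, end = max(nums),
        strand = strand, feature_kind = key,
        product = qual("product"), protein_seq = trans,
        stringsAsFactors = FALSE)
    }
    contigs[[r]] <- data.frame(contig_id = contig_id, length = clen,
                               stringsAsFactors = FALSE)
    seqs[contig_id] <- seq
  }
  gene_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(), contig_id = character(),
               start = integer(), end = integer(), strand = character(),
               feature_kind = character(), product = character(),
               protein_seq = character(), stringsAsFactors = FALSE)
  annotated_genome(genome_id, do.call(rbind, contigs), gene_df,
                   source, taxon_label,
                   contig_seqs = if (all(nzchar(seqs))) seqs else NULL)
}

#' Write a genome as a GenBank flat file
#'
#' @param genome An `annotated_genome` with contig sequences.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genbank <- function(genome, path) {
  if (is.null(genome$contig_seqs)) {
    stop_bad("genome %s carries no contig sequences", genome$genome_id)
  }
  con <- file(path, "w"); on.exit(close(con))
  wrap_qual <- function(name, value) {
    txt <- sprintf('/%s="%s"', name, value)
    out <- character(0)
    while (nchar(txt) > 58) {
      out <- c(out, paste0(strrep(" ", 21), substr(txt, 1, 58)))
      txt <- substr(txt, 59, nchar(txt))
    }
    c(out, paste0(strrep(" ", 21), txt))
  }
  for (ci in seq_len(nrow(genome$contigs))) {
    cid <- genome$contigs$contig_id[ci]
    clen <- genome$contigs$length[ci]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", cid, clen), con)
    writeLines(sprintf("DEFINITION  %s contig %s.", genome$genome_id, cid), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- contig_genes(genome, cid)
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", g$feature_kind[i], loc), con)
      writeLines(wrap_qual("locus_tag", g$gene_id[i]), con)
      if (nzchar(g$product[i])) writeLines(wrap_qual("product", g$product[i]), con)
      if (g$feature_kind[i] == "CDS" && nzchar(g$protein_seq[i])) {
        writeLines(wrap_qual("translation", g$protein_seq[i]), con)
      }
    }
    writeLines("ORIGIN", con)
    seq <- genome$contig_seqs[[cid]]
    pos <- seq(1, nchar(seq), by = 60)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59, nchar(seq)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tolower(tens), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write the pipeline report file set
#'
#' Serialises a completed result bundle as TSV tables plus a JSON run
#' manifest. Fails before writing anything if the directory cannot be
#' created.
#'
#' @param results A result bundle from [run_all()] (or a compatible list
#'   with elements `clusters`, `subtypes`, `islands`, `genotypes`,
#'   `presence`, `repertoires`, `effectors`, `config`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_reports <- function(results, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_bad("cannot create output directory %s", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  if (!isTRUE(file.create(probe, showWarnings = FALSE))) {
    stop_bad("output directory %s is not writable", out_dir)
  }
  unlink(probe)
  files <- character(0)
  put <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv_plain(df, p)
    files <<- c(files, p)
  }

  cl <- results$clusters
  cluster_tab <- if (!is.null(cl) && nrow(cl)) {
    data.frame(
      cluster_id = cl$cluster_id, genome_id = cl$genome_id,
      contig_id = cl$contig_id,
      span_start = cl$span_start + 1L, span_end = cl$span_end,
      core_count = cl$core_count,
      core_present = vapply(cl$core_present, paste, "", collapse = ","),
      accessory = vapply(cl$accessory, function(a)
        paste(sprintf("%s:%s", a$gene_id, a$family), collapse = ","), ""),
      truncated = cl$truncated, complete = cl$complete,
      system_label = cl$system_label %||% "",
      subtype = cl$subtype %||% "",
      stringsAsFactors = FALSE)
  } else {
    data.frame(cluster_id = character(), genome_id = character(),
               contig_id = character(), span_start = integer(),
               span_end = integer(), core_count = integer(),
               core_present = character(), accessory = character(),
               truncated = character(), complete = logical(),
               system_label = character(), subtype = character())
  }
  put(cluster_tab, "clusters.tsv")

  geno <- results$genotypes
  if (is.null(geno) || !nrow(geno)) {
    geno <- data.frame(genome_id = character(), genotype = integer(),
                       archetype = character(), island_status = character(),
                       island_length_bp = integer())
  }
  put(geno, "genotypes.tsv")

  if (!is.null(results$presence)) {
    pm <- results$presence$matrix
    prev <- round(100 * colMeans(pm), 1)
    pm_df <- data.frame(genome_id = rownames(pm),
                        as.data.frame(pm, check.names = FALSE),
                        check.names = FALSE)
    hdr <- data.frame(genome_id = "prevalence_pct",
                      as.data.frame(t(prev), check.names = FALSE),
                      check.names = FALSE)
    put(rbind(hdr, pm_df), "presence_matrix.tsv")
  }
  if (!is.null(results$subtypes)) put(results$subtypes, "subtypes.tsv")
  if (!is.null(results$repertoires)) put(results$repertoires, "repertoires.tsv")
  if (!is.null(results$effectors)) put(results$effectors, "effectors.tsv")
  if (!is.null(results$islands_table)) put(results$islands_table, "islands.tsv")
  if (!is.null(results$tree)) {
    p <- file.path(out_dir, "sheath_tree.nwk")
    ape::write.tree(results$tree, p)
    files <- c(files, p)
  }
  manifest <- list(tool = "t6sscan",
                   version = as.character(utils::packageVersion("t6sscan")),
                   config = results$config,
                   n_genomes = results$n_genomes %||% NA,
                   files = basename(files))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, mp))
}
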