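# Gene-family assignment: maps genes to the closed T6SS vocabulary (13 core
# genes tssA-tssM, accessory families, VipA/VipB sheath domains) from
# HMMER3 domtblout-style hit tables, or via a naive alignment-based
# assigner for desk-scale fixtures.

#' The 13 core T6SS gene families
#' @return Character vector `tssA` ... `tssM`.
#' @export
t6ss_core_families <- function() paste0("tss", LETTERS[1:13])

#' Accessory T6SS gene families recognised by the pipeline
#' @return Character vector of accessory family tokens.
#' @export
t6ss_accessory_families <- function() {
  c("PAAR", "FHA", "Pkinase", "PP2C", "DUF4150",
    "tasL", "tasR", "vasH", "impE", "tagF")
}

#' Sheath Pfam domain families
#' @return `VipA` (PF05591, small subunit) and `VipB` (PF05943, large
#'   subunit).
#' @export
sheath_domain_families <- function() c("VipA", "VipB")

#' The full closed family vocabulary
#' @param extra Additional family tokens admitted via a name map.
#' @return Character vector of all recognised family tokens.
#' @export
family_vocabulary <- function(extra = character(0)) {
  unique(c(t6ss_core_families(), t6ss_accessory_families(),
           sheath_domain_families(), extra))
}

#' Load family hits from an HMMER3 domtblout table
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmsearch --domtblout`. The target name column is the gene id and the
#' query name column is the profile name, mapped to a family token via
#' `name_map`. One hit is emitted per domain line whose independent E-value
#' passes `max_evalue`.
#'
#' @param path domtblout file.
#' @param name_map Optional named character: profile name -> family token.
#'   By default profile names are used directly.
#' @param max_evalue Inclusion threshold on the domain independent E-value.
#' @param strict If `TRUE`, a profile name outside the vocabulary is an
#'   error; otherwise such lines are skipped with a warning.
#' @param extra_families Extra vocabulary tokens (see [family_vocabulary()]).
#' @return `data.frame` of family hits: `gene_id`, `family`, `score`,
#'   `evalue`, `ali_start`, `ali_end` (0-based half-open on the protein).
#' @export
load_domtbl <- function(path, name_map = NULL, max_evalue = 1e-5,
                        strict = FALSE, extra_families = character(0)) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  vocab <- family_vocabulary(c(extra_families, unname(name_map)))
  hits <- lapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 22) stop_bad("malformed domtblout line: %s", l)
    fam <- f[[4]]
    if (!is.null(name_map) && fam %in% names(name_map)) fam <- name_map[[fam]]
    data.frame(gene_id = f[[1]], family = fam,
               score = as.numeric(f[[14]]), evalue = as.numeric(f[[13]]),
               ali_start = as.integer(f[[18]]) - 1L,
               ali_end = as.integer(f[[19]]),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, c(hits, list(empty_hits())))
  unknown <- !(hits$family %in% vocab)
  if (any(unknown)) {
    if (strict) stop_bad("unknown family token '%s'", hits$family[unknown][[1]])
    warning(sprintf("skipping %d hit(s) with unknown family tokens",
                    sum(unknown)), call. = FALSE)
    hits <- hits[!unknown, , drop = FALSE]
  }
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(gene_id = character(), family = character(),
             score = numeric(), evalue = numeric(),
             ali_start = integer(), ali_end = integer(),
             stringsAsFactors = FALSE)
}

#' Resolve family hits into a per-gene family map
#'
#' Each gene receives at most one core-family label (its highest-scoring
#' core hit; score ties resolved alphabetically by family token) and any
#' number of accessory labels. Sheath domain hits (VipA/VipB) are kept per
#' protein, sorted by alignment start; of any pair overlapping more than
#' half of the shorter hit, only the higher-scoring one survives.
#'
#' @param genome An `annotated_genome`.
#' @param hits Family hit table (see [load_domtbl()] / [naive_assign()]).
#' @return A `family_map`: list with `core` (named character, gene_id ->
#'   family, `NA` if none), `accessory` (`data.frame` gene_id/family) and
#'   `domains` (`data.frame` of resolved VipA/VipB hits).
#' @export
assign_families <- function(genome, hits) {
  unknown <- setdiff(hits$gene_id, genome$genes$gene_id)
  if (length(unknown)) {
    stop_bad("hit references unknown gene id %s", unknown[[1]])
  }
  core_fams <- t6ss_core_families()
  acc_fams <- t6ss_accessory_families()
  dom_fams <- sheath_domain_families()

  core <- stats::setNames(rep(NA_character_, nrow(genome$genes)),
                          genome$genes$gene_id)
  ch <- hits[hits$family %in% core_fams, , drop = FALSE]
  if (nrow(ch)) {
    ch <- ch[order(ch$gene_id, -ch$score, ch$family), , drop = FALSE]
    best <- ch[!duplicated(ch$gene_id), , drop = FALSE]
    core[best$gene_id] <- best$family
  }

  ah <- hits[hits$family %in% acc_fams, c("gene_id", "family"), drop = FALSE]
  ah <- unique(ah)
  ah <- ah[order(ah$gene_id, ah$family), , drop = FALSE]
  rownames(ah) <- NULL

  dh <- hits[hits$family %in% dom_fams, , drop = FALSE]
  dh <- do.call(rbind, c(lapply(split(dh, dh$gene_id), resolve_domain_overlaps),
                         list(empty_hits())))
  rownames(dh) <- NULL

  structure(list(core = core, accessory = ah, domains = dh,
                 genome_id = genome$genome_id),
            class = "family_map")
}

# Drop, from any pair of domain hits on one protein overlapping > 50% of the
# shorter hit, the lower-scoring hit. Returns hits sorted by ali_start.
resolve_domain_overlaps <- function(h) {
  h <- h[order(-h$score, h$ali_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(h))) {
      if (j <= i || !keep[j]) next
      ov <- min(h$ali_end[i], h$ali_end[j]) - max(h$ali_start[i], h$ali_start[j])
      shorter <- min(h$ali_end[i] - h$ali_start[i], h$ali_end[j] - h$ali_start[j])
      if (ov > 0.5 * shorter) keep[j] <- FALSE
    }
  }
  h <- h[keep, , drop = FALSE]
  h[order(h$ali_start, h$ali_end, h$family), , drop = FALSE]
}

#' Core family label of one gene
#' @param family_map A `family_map`.
#' @param gene_id Gene id.
#' @return Family token or `NA`.
#' @export
core_label <- function(family_map, gene_id) {
  unname(family_map$core[gene_id])
}

#' Naive alignment-based family assigner for fixtures
#'
#' A desk-scale stand-in for a profile search: every protein is locally
#' aligned against one consensus sequence per family, and a hit is emitted
#' when the alignment identity and E-value pass the thresholds. The E-value
#' treats the whole consensus panel as the search database.
#'
#' @param genome An `annotated_genome`.
#' @param family_consensus Named character vector (or `AAStringSet`) of one
#'   consensus protein per family token.
#' @param min_identity Minimum alignment-column identity (default 0.5).
#' @param max_evalue Maximum E-value (default 1e-5).
#' @return Family hit table in [load_domtbl()] layout.
#' @export
naive_assign <- function(genome, family_consensus, min_identity = 0.5,
                         max_evalue = 1e-5) {
  if (inherits(family_consensus, "AAStringSet")) {
    family_consensus <- stats::setNames(as.character(family_consensus),
                                        names(family_consensus))
  }
  if (!length(family_consensus)) stop_bad("empty consensus set")
  if (is.null(names(family_consensus)) || !all(nzchar(names(family_consensus)))) {
    stop_bad("family consensus sequences must be named by family token")
  }
  db_res <- sum(nchar(family_consensus))
  cds <- genome$genes[genome$genes$feature_kind == "CDS" &
                        nzchar(genome$genes$protein_seq), , drop = FALSE]
  if (!nrow(cds)) return(empty_hits())
  prots <- stats::setNames(cds$protein_seq, cds$gene_id)
  res <- align_sets(prots, family_consensus, type = "local")
  res$evalue <- evalue(res$bit_score,
                       nchar(prots)[match(res$query_id, names(prots))],
                       db_res)
  pass <- !is.na(res$identity) & res$identity >= min_identity &
    res$evalue <= max_evalue
  r <- res[pass, , drop = FALSE]
  out <- data.frame(
    gene_id = r$query_id, family = r$subject_id,
    score = r$bit_score, evalue = r$evalue,
    # alignment coordinates on the protein are not tracked by the
    # vectorised screen; report the full-protein envelope
    ali_start = rep(0L, nrow(r)),
    ali_end = nchar(prots)[match(r$query_id, names(prots))],
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write family hits as an HMMER3-style domtblout table
#'
#' Emits the 22-column per-domain table dialect that [load_domtbl()]
#' consumes (one line per hit, full-protein envelope).
#'
#' @param hits Family hit table.
#' @param genome An `annotated_genome` (for target lengths).
#' @param path Output file.
#' @return Invisibly, the path.
#' @export
write_domtbl <- function(hits, genome, path) {
  plen <- stats::setNames(nchar(genome$genes$protein_seq),
                          genome$genes$gene_id)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target", con)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    tl <- unname(plen[h$gene_id])
    writeLines(sprintf(
      "%s - %d %s - %d %.2g %.1f 0.0 1 1 %.2g %.2g %.1f 0.0 1 %d %d %d %d %d 0.99 -",
      h$gene_id, tl, h$family, h$ali_end - h$ali_start,
      h$evalue, h$score, h$evalue, h$evalue, h$score,
      h$ali_end - h$ali_start, h$ali_start + 1L, h$ali_end,
      h$ali_start + 1L, h$ali_end), con)
  }
  invisible(path)
}
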