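# Sheath-protein domain architecture: classify each sheath-domain-bearing
# protein from its ordered VipA/VipB domain string, report fused-domain
# identities against the standalone subunits, classify per-cluster sheath
# repertoires (standard / TssC_L fusion / tssC duplication), and run the
# threshold-based effector similarity screen.

#' Classify a protein from its ordered sheath-domain string
#'
#' Rules over the position-sorted VipA/VipB domain hits: at least two VipA
#' and at least one VipB is the TssC_L fusion signature; VipA only is
#' TssB-like; VipB only is TssC-like; a single VipA plus VipB (or no sheath
#' domain at all) is `other`.
#'
#' @param domain_hits Resolved, position-sorted VipA/VipB hits of one
#'   protein (rows of a `family_map$domains` table).
#' @return An `architecture_call`: list with `protein_id`, `domain_string`,
#'   `call`, and the `domains` table.
#' @export
scan_architecture <- function(domain_hits) {
  pid <- if (nrow(domain_hits)) domain_hits$gene_id[[1]] else NA_character_
  ds <- domain_hits$family
  nA <- sum(ds == "VipA"); nB <- sum(ds == "VipB")
  call <- if (nA >= 2 && nB >= 1) "TssC_L_fusion"
  else if (nA >= 1 && nB == 0) "TssB_like"
  else if (nB >= 1 && nA == 0) "TssC_like"
  else "other"
  structure(list(protein_id = pid, domain_string = ds, call = call,
                 domains = domain_hits),
            class = "architecture_call")
}

#' Architecture calls for every domain-bearing protein of a genome
#'
#' @param family_map A `family_map`.
#' @return Named list of `architecture_call`s, one per protein with sheath
#'   domain hits.
#' @export
scan_architectures <- function(family_map) {
  d <- family_map$domains
  if (!nrow(d)) return(list())
  lapply(split(d, d$gene_id), scan_architecture)
}

#' Identity report of fused sheath domains against the standalone subunits
#'
#' For a TssC_L fusion within a cluster that also carries standalone TssB
#' and TssC proteins: each fused VipA domain instance (extracted by its
#' hit envelope) is globally aligned against TssB's VipA domain, and the
#' fused VipB instance against TssC's VipB domain. Missing standalone
#' partners omit that comparison with a reason.
#'
#' @param fusion_call An `architecture_call` with call `TssC_L_fusion`.
#' @param proteins Named character of the cluster's proteins (must include
#'   the fusion protein).
#' @param calls List of `architecture_call`s for the cluster's sheath
#'   proteins (to locate the standalone TssB/TssC and their envelopes).
#' @return List with `report` (`data.frame`: `domain`, `instance`,
#'   `partner_protein`, `identity`, `evalue`) and `omitted` (reasons).
#' @export
domain_identity_report <- function(fusion_call, proteins, calls) {
  stopifnot(fusion_call$call == "TssC_L_fusion")
  fus_seq <- proteins[[fusion_call$protein_id]]
  if (is.null(fus_seq)) stop_bad("fusion protein %s not in supplied proteins",
                                 fusion_call$protein_id)
  standalone <- function(want) {
    for (cl in calls) {
      if (cl$call == want && cl$protein_id != fusion_call$protein_id) return(cl)
    }
    NULL
  }
  tssB <- standalone("TssB_like")
  tssC <- standalone("TssC_like")
  slice <- function(seq, d) substr(seq, d$ali_start + 1L, d$ali_end)
  rows <- list(); omitted <- character(0)
  compare <- function(fd, instance, partner_call, partner_family) {
    if (is.null(partner_call)) {
      omitted <<- c(omitted, sprintf(
        "%s instance %d: no standalone %s partner in cluster",
        fd$family, instance, if (fd$family == "VipA") "TssB" else "TssC"))
      return()
    }
    pd <- partner_call$domains
    pd <- pd[pd$family == fd$family, , drop = FALSE]
    if (!nrow(pd)) {
      omitted <<- c(omitted, sprintf(
        "%s instance %d: partner %s has no %s envelope", fd$family, instance,
        partner_call$protein_id, fd$family))
      return()
    }
    a <- slice(fus_seq, fd)
    b <- slice(proteins[[partner_call$protein_id]], pd[1, ])
    aln <- global_align(a, b)
    rows[[length(rows) + 1L]] <<- data.frame(
      domain = fd$family, instance = instance,
      partner_protein = partner_call$protein_id,
      identity = aln$identity,
      evalue = evalue(aln$bit_score, nchar(a), nchar(b)),
      stringsAsFactors = FALSE)
  }
  d <- fusion_call$domains
  ai <- 0L; bi <- 0L
  for (i in seq_len(nrow(d))) {
    if (d$family[i] == "VipA") {
      ai <- ai + 1L
      compare(d[i, ], ai, tssB, "VipA")
    } else {
      bi <- bi + 1L
      compare(d[i, ], bi, tssC, "VipB")
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain = character(), instance = integer(),
               partner_protein = character(), identity = numeric(),
               evalue = numeric(), stringsAsFactors = FALSE)
  list(report = report, omitted = omitted)
}

#' Classify a cluster's sheath-gene repertoire
#'
#' Fusion if any member protein carries the TssC_L signature; duplication
#' if at least two TssC-like proteins and no fusion (their pairwise
#' global-alignment identity is reported); standard for exactly one
#' TssB-like plus one TssC-like; `other` otherwise.
#'
#' @param cluster One row of a cluster table.
#' @param calls List of `architecture_call`s covering the cluster's genes.
#' @param proteins Named character of member protein sequences (needed for
#'   the duplication identity; optional otherwise).
#' @return A `repertoire_call`: list with `cluster_id`, `pattern`,
#'   `tssB_like`, `tssC_like`, `fusions`, `tssC_pairwise_identity`.
#' @export
classify_repertoire <- function(cluster, calls, proteins = NULL) {
  ids <- cluster$gene_ids[[1]]
  calls <- Filter(function(cl) cl$protein_id %in% ids, calls)
  by_call <- function(want) vapply(Filter(function(cl) cl$call == want, calls),
                                   function(cl) cl$protein_id, "")
  bs <- by_call("TssB_like"); cs <- by_call("TssC_like")
  fus <- by_call("TssC_L_fusion")
  pattern <- if (length(fus)) "fusion"
  else if (length(cs) >= 2) "duplication"
  else if (length(bs) == 1 && length(cs) == 1) "standard"
  else "other"
  pw <- NA_real_
  if (pattern == "duplication" && !is.null(proteins) &&
      all(cs[1:2] %in% names(proteins))) {
    pw <- global_align(proteins[[cs[[1]]]], proteins[[cs[[2]]]])$identity
  }
  structure(list(cluster_id = cluster$cluster_id, pattern = pattern,
                 tssB_like = bs, tssC_like = cs, fusions = fus,
                 tssC_pairwise_identity = pw),
            class = "repertoire_call")
}

#' Effector similarity screen against a reference database
#'
#' Locally aligns every query against every database protein and keeps the
#' best hit per query-subject pair when BOTH thresholds pass: alignment
#' identity `>= min_identity` and E-value `<= max_evalue` (both inclusive).
#' E-values use the total database residue count. Hits are sorted by
#' E-value, ties by descending bit score.
#'
#' @param query_proteins Named character of query proteins.
#' @param effector_db Named character (or `AAStringSet`) of reference
#'   effector proteins.
#' @param min_identity Identity threshold (default 0.30).
#' @param max_evalue E-value threshold (default 1e-6).
#' @return `data.frame`: `query_id`, `db_protein_id`, `identity`,
#'   `aln_len`, `evalue`, `bit_score`, `coverage`.
#' @export
search_effectors <- function(query_proteins, effector_db,
                             min_identity = 0.30, max_evalue = 1e-6) {
  if (inherits(effector_db, "AAStringSet")) {
    effector_db <- stats::setNames(as.character(effector_db), names(effector_db))
  }
  if (!length(effector_db)) stop_bad("empty effector database")
  if (!length(query_proteins)) stop_bad("empty query set")
  db_res <- sum(nchar(effector_db))
  res <- align_sets(query_proteins, effector_db, type = "local")
  res$evalue <- evalue(res$bit_score, nchar(query_proteins)[
    match(res$query_id, names(query_proteins))], db_res)
  pass <- !is.na(res$identity) & res$identity >= min_identity &
    res$evalue <= max_evalue
  r <- res[pass, , drop = FALSE]
  hits <- data.frame(
    query_id = r$query_id, db_protein_id = r$subject_id,
    identity = r$identity, aln_len = r$aln_len,
    evalue = r$evalue, bit_score = r$bit_score,
    coverage = r$query_coverage,
    stringsAsFactors = FALSE)
  hits <- hits[order(hits$evalue, -hits$bit_score,
                     hits$query_id, hits$db_protein_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
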