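# Pairwise protein alignment engine: global (Needleman-Wunsch) and local
# (Smith-Waterman) alignment with affine gaps, percent identity under two
# denominator conventions, and BLAST-style bit scores / E-values. The DP is
# delegated to Biostrings::pairwiseAlignment; scoring conventions here are
# the BLASTP defaults (BLOSUM62, gap open 11, gap extend 1, so a gap of
# length L costs 11 + L).

# Karlin-Altschul constants for gapped BLOSUM62 11/1 searches.
KA_LAMBDA <- 0.267
KA_K <- 0.041

get_submatrix <- function(substitution_matrix) {
  if (is.matrix(substitution_matrix)) return(substitution_matrix)
  if (is.character(substitution_matrix) && length(substitution_matrix) == 1) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    return(get(substitution_matrix, envir = e))
  }
  stop_bad("substitution_matrix must be a matrix or a Biostrings matrix name")
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-delimited square matrix format distributed with
#' BLAST (`#` comment lines, one header row of residue letters, one labelled
#' row per residue).
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  lab <- vapply(rows, `[`, character(1), 1)
  vals <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  dimnames(vals) <- list(lab, header)
  vals
}

new_alignment <- function(query_id, subject_id, qaln, saln, score,
                          query_len, subject_len, type) {
  stopifnot(nchar(qaln) == nchar(saln))
  qres <- nchar(gsub("-", "", qaln))
  sres <- nchar(gsub("-", "", saln))
  aln <- structure(
    list(query_id = query_id, subject_id = subject_id,
         query_aln = qaln, subject_aln = saln,
         score = score,
         bit_score = bit_score(score),
         query_len = query_len, subject_len = subject_len,
         query_coverage = qres / query_len,
         subject_coverage = sres / subject_len,
         type = type),
    class = "t6ss_alignment")
  aln$identity <- percent_identity(aln)
  aln
}

#' @export
print.t6ss_alignment <- function(x, ...) {
  cat(sprintf("%s alignment %s vs %s\n", x$type, x$query_id, x$subject_id))
  cat(sprintf("  score %.1f (%.1f bits), identity %s, coverage %.2f/%.2f\n",
              x$score, x$bit_score,
              if (is.na(x$identity)) "NA" else sprintf("%.3f", x$identity),
              x$query_coverage, x$subject_coverage))
  cat("  ", x$query_aln, "\n  ", x$subject_aln, "\n", sep = "")
  invisible(x)
}

align_pair <- function(a, b, substitution_matrix, gap_open, gap_extend, type) {
  if (!nzchar(a) || !nzchar(b)) stop_bad("cannot align an empty sequence")
  qid <- names(a) %||% "query"; sid <- names(b) %||% "subject"
  qid <- if (is.null(names(a)) || !nzchar(names(a)[1])) "query" else names(a)[1]
  sid <- if (is.null(names(b)) || !nzchar(names(b)[1])) "subject" else names(b)[1]
  mat <- get_submatrix(substitution_matrix)
  pa <- Biostrings::pairwiseAlignment(
    unname(a), unname(b), type = type, substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (type == "local" && sc <= 0) {
    # No positive-scoring local pair: empty alignment, score 0 by convention.
    return(new_alignment(qid, sid, "", "", 0, nchar(a), nchar(b), type))
  }
  new_alignment(qid, sid,
                as.character(Biostrings::alignedPattern(pa)),
                as.character(Biostrings::alignedSubject(pa)),
                sc, nchar(a), nchar(b), type)
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' Optimal global alignment with affine gap penalties; a gap of length L
#' costs `gap_open + gap_extend * L`.
#'
#' @param a,b Amino-acid strings (optionally named; names become ids).
#' @param substitution_matrix Matrix or Biostrings matrix name
#'   (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (BLASTP defaults 11, 1).
#' @return A `t6ss_alignment` object: aligned strings, raw and bit score,
#'   identity fraction and coverages.
#' @export
global_align <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1) {
  align_pair(a, b, substitution_matrix, gap_open, gap_extend, "global")
}

#' Local (Smith-Waterman) protein alignment
#'
#' Optimal local alignment; when no residue pair scores positive the empty
#' alignment with score 0 is returned.
#'
#' @inheritParams global_align
#' @return A `t6ss_alignment` object.
#' @export
local_align <- function(a, b, substitution_matrix = "BLOSUM62",
                        gap_open = 11, gap_extend = 1) {
  align_pair(a, b, substitution_matrix, gap_open, gap_extend, "local")
}

#' Convert a raw alignment score to a bit score
#'
#' Karlin-Altschul conversion `(lambda * S - ln K) / ln 2` with the standard
#' gapped BLOSUM62 11/1 constants.
#'
#' @param raw_score Raw alignment score.
#' @param lambda,K Karlin-Altschul parameters.
#' @return Bit score.
#' @export
bit_score <- function(raw_score, lambda = KA_LAMBDA, K = KA_K) {
  (lambda * raw_score - log(K)) / log(2)
}

#' BLAST-style E-value from a bit score
#'
#' `E = m * n * 2^(-bit_score)` with m the query length and n the total
#' residue count of the searched database.
#'
#' @param bit_score Bit score (see [bit_score()]).
#' @param query_len Query length in residues.
#' @param db_residues Total database residues.
#' @return Expected number of chance hits at this score.
#' @export
evalue <- function(bit_score, query_len, db_residues) {
  if (any(query_len <= 0) || any(db_residues <= 0)) {
    stop_bad("query_len and db_residues must be positive")
  }
  query_len * db_residues * 2^(-bit_score)
}

#' Percent identity of an alignment
#'
#' Matches divided by the denominator named by `convention`:
#' `"alignment_columns"` counts every alignment column (gaps included),
#' `"shorter_sequence"` divides by the shorter input sequence length.
#' A zero-length alignment has undefined identity and returns `NA`.
#'
#' @param alignment A `t6ss_alignment`.
#' @param convention Denominator convention.
#' @return Identity fraction in `[0, 1]`, or `NA` for an empty alignment.
#' @export
percent_identity <- function(alignment,
                             convention = c("alignment_columns",
                                            "shorter_sequence")) {
  convention <- match.arg(convention)
  q <- strsplit(alignment$query_aln, "")[[1]]
  s <- strsplit(alignment$subject_aln, "")[[1]]
  if (length(q) == 0) return(NA_real_)
  matches <- sum(q == s & q != "-")
  denom <- switch(convention,
                  alignment_columns = length(q),
                  shorter_sequence = min(alignment$query_len,
                                         alignment$subject_len))
  matches / denom
}

# Vectorised one-vs-many alignment used by the screening stages. Returns a
# data.frame of scores/identities without materialising alignment strings:
# alignment columns are recovered exactly as
#   columns = query_residues + subject_residues - (matches + mismatches)
# since every column consumes a residue of the query and/or the subject and
# match/mismatch columns consume one of each. For global alignments the
# residue counts are the full sequence lengths (end gaps included in the
# column count); for local alignments they are the aligned span widths.
align_many <- function(query, subjects, type = "local",
                       substitution_matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  stopifnot(length(query) == 1, length(subjects) >= 1)
  mat <- get_submatrix(substitution_matrix)
  subj <- Biostrings::AAStringSet(unname(subjects))
  pa <- Biostrings::pairwiseAlignment(
    rep(unname(query), length(subj)), subj, type = type,
    substitutionMatrix = mat, gapOpening = gap_open, gapExtension = gap_extend)
  alignment_stats(pa, type,
                  qlen = rep(nchar(query), length(subjects)),
                  slen = nchar(subjects),
                  subject_id = names(subjects) %||%
                    as.character(seq_along(subjects)))
}

# Shared fast-accessor summary for a PairwiseAlignments object.
alignment_stats <- function(pa, type, qlen, slen, subject_id,
                            query_id = NULL) {
  sc <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  if (type == "global") {
    qres <- qlen; sres <- slen
  } else {
    qres <- Biostrings::width(Biostrings::pattern(pa))
    sres <- Biostrings::width(Biostrings::subject(pa))
  }
  ncol_aln <- qres + sres - (nm + nmm)
  empty <- type == "local" & sc <= 0
  sc[empty] <- 0; ncol_aln[empty] <- 0L; nm[empty] <- 0L
  qres[empty] <- 0L; sres[empty] <- 0L
  out <- data.frame(
    subject_id = subject_id,
    score = sc,
    bit_score = bit_score(sc),
    identity = ifelse(ncol_aln > 0, nm / ncol_aln, NA_real_),
    aln_len = ncol_aln,
    query_coverage = qres / qlen,
    subject_coverage = sres / slen,
    stringsAsFactors = FALSE)
  if (!is.null(query_id)) out <- cbind(query_id = query_id, out,
                                       stringsAsFactors = FALSE)
  out
}

# Batched all-vs-all screen: one pairwiseAlignment call per subject with
# the whole query set as patterns (per-call overhead dominates per-pair
# cost for large query sets).
align_sets <- function(queries, subjects, type = "local",
                       substitution_matrix = "BLOSUM62",
                       gap_open = 11, gap_extend = 1) {
  stopifnot(length(queries) >= 1, length(subjects) >= 1)
  mat <- get_submatrix(substitution_matrix)
  qset <- Biostrings::AAStringSet(unname(queries))
  qids <- names(queries) %||% as.character(seq_along(queries))
  out <- vector("list", length(subjects))
  for (j in seq_along(subjects)) {
    pa <- Biostrings::pairwiseAlignment(
      qset, unname(subjects[[j]]), type = type,
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
    out[[j]] <- alignment_stats(
      pa, type, qlen = nchar(queries),
      slen = rep(nchar(subjects[[j]]), length(queries)),
      subject_id = rep((names(subjects) %||%
                          as.character(seq_along(subjects)))[[j]],
                       length(queries)),
      query_id = qids)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
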