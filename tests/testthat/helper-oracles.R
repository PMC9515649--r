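# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# ---- affine-gap alignment oracles (Gotoh three-state DP) ------------------
# Convention matches the package: a gap of length L costs open + ext * L.

oracle_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

oracle_global_score <- function(a, b, mat = oracle_matrix(),
                                open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)  # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)  # ends in gap in a (b consumed)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracle_local_score <- function(a, b, mat = oracle_matrix(),
                               open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0, max(M[i, j], X[i, j], Y[i, j]) + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive recursive enumeration of every global alignment (no DP reuse);
# only tractable for very short strings.
oracle_enumerate_global <- function(a, b, mat = oracle_matrix(),
                                    open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      cost <- if (state == "x") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j <= length(bv)) {
      cost <- if (state == "y") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# ---- cluster-calling oracle ----------------------------------------------
# Independent derivation: enumerate every (first, last) pair of core-gene
# positions, keep intervals that are internally valid (every adjacent core
# pair separated by <= max_gap non-core genes), maximal (no core within
# max_gap beyond either end), and rich enough (>= min_core distinct
# families). Returns a list of c(first_gene_index, last_gene_index).
oracle_scan <- function(fams, min_core, max_gap) {
  pos <- which(fams != "x" & nzchar(fams))
  out <- list()
  for (ai in seq_along(pos)) {
    for (bi in ai:length(pos)) {
      p <- pos[ai:bi]
      if (length(p) > 1 && any(diff(p) - 1 > max_gap)) next
      if (ai > 1 && (p[1] - pos[ai - 1] - 1) <= max_gap) next
      if (bi < length(pos) && (pos[bi + 1] - p[length(p)] - 1) <= max_gap) next
      if (length(unique(fams[p])) < min_core) next
      out[[length(out) + 1]] <- c(p[1], p[length(p)])
    }
  }
  out
}

# ---- quick fixture builders ----------------------------------------------

random_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, TRUE),
        collapse = "")
}

# Genome with one contig whose genes carry the given family labels ("x" or
# "" for unlabelled); proteins are single residues unless supplied.
toy_genome <- function(fams, genome_id = "G", contig_id = "c1",
                       proteins = NULL) {
  n <- length(fams)
  genes <- data.frame(
    gene_id = sprintf("%s_%03d", genome_id, seq_len(n)),
    contig_id = contig_id,
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+", feature_kind = "CDS", product = "protein",
    protein_seq = proteins %||% rep("MKT", n),
    stringsAsFactors = FALSE)
  contigs <- data.frame(contig_id = contig_id, length = n * 1000L + 500L,
                        stringsAsFactors = FALSE)
  annotated_genome(genome_id, contigs, genes)
}

# Family map straight from a label vector (bypasses hit tables).
toy_family_map <- function(genome, fams,
                           accessory = NULL, domains = NULL) {
  core <- ifelse(fams %in% t6sscan::t6ss_core_families(), fams, NA_character_)
  structure(list(
    core = stats::setNames(core, genome$genes$gene_id),
    accessory = accessory %||% data.frame(gene_id = character(),
                                          family = character(),
                                          stringsAsFactors = FALSE),
    domains = domains %||% data.frame(gene_id = character(),
                                      family = character(), score = numeric(),
                                      evalue = numeric(), ali_start = integer(),
                                      ali_end = integer(),
                                      stringsAsFactors = FALSE),
    genome_id = genome$genome_id), class = "family_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fast path for the many thousands of scans in the oracle sweeps: builds
# the gene table and family map directly, skipping genome validation.
scan_labels <- function(fams, min_core = 4, max_gap = 10) {
  n <- length(fams)
  ids <- sprintf("G_%03d", seq_len(n))
  genes <- data.frame(
    gene_id = ids, contig_id = "c1",
    start = (seq_len(n) - 1L) * 1000L,
    end = (seq_len(n) - 1L) * 1000L + 900L,
    strand = "+", feature_kind = "CDS", product = "protein",
    protein_seq = "MKT", stringsAsFactors = FALSE)
  core <- ifelse(fams %in% t6sscan::t6ss_core_families(), fams, NA_character_)
  fm <- structure(list(
    core = stats::setNames(core, ids),
    accessory = data.frame(gene_id = character(), family = character(),
                           stringsAsFactors = FALSE),
    domains = data.frame(gene_id = character(), family = character(),
                         score = numeric(), evalue = numeric(),
                         ali_start = integer(), ali_end = integer(),
                         stringsAsFactors = FALSE),
    genome_id = "G"), class = "family_map")
  scan_contig(genes, fm, min_core = min_core, max_gap = max_gap,
              genome_id = "G")
}

# Compare scan_labels with oracle_scan on one string; returns TRUE on
# agreement (used to aggregate sweeps into a single expectation).
scan_agrees <- function(fams, min_core, max_gap) {
  fams <- unname(fams)
  got <- scan_labels(fams, min_core = min_core, max_gap = max_gap)
  want <- lapply(oracle_scan(fams, min_core = min_core, max_gap = max_gap),
                 unname)
  if (nrow(got) != length(want)) return(FALSE)
  if (!nrow(got)) return(TRUE)
  spans <- lapply(seq_len(nrow(got)), function(k) {
    idx <- match(got$gene_ids[[k]], sprintf("G_%03d", seq_along(fams)))
    c(min(idx), max(idx))
  })
  identical(spans, want)
}
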