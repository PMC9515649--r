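# Cluster calling: the core-count and spacing rule, its boundary behaviour,
# agreement with an independent segmentation oracle, and the completeness /
# system-labelling helpers.

x <- "x"

test_that("a run with four distinct core families is called, three is not", {
  cl <- scan_labels(c("tssB", x, "tssC", x, "tssK", "tssL"))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$core_present[[1]], c("tssB", "tssC", "tssK", "tssL"))
  expect_equal(cl$core_count, 4)
  # three distinct families, even with four core genes, is rejected
  expect_equal(nrow(scan_labels(c("tssB", "tssB", "tssC", "tssK"))), 0)
})

test_that("a 10-gene gap merges and an 11-gene gap splits", {
  merged <- scan_labels(c("tssB", rep(x, 10), "tssC", "tssK", "tssL"))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$core_count, 4)
  split <- scan_labels(c("tssB", rep(x, 11), "tssC", "tssK", "tssL"))
  expect_equal(nrow(split), 0)  # fragments have 1 and 3 families
})

test_that("tandem copies of one family never satisfy min_core", {
  expect_equal(nrow(scan_labels(rep("tssD", 8))), 0)
  # but tandem copies inside a rich run do not block the call
  cl <- scan_labels(c("tssD", "tssD", "tssD", "tssB", "tssC", "tssK"))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$core_count, 4)
})

test_that("scan agrees with the exhaustive segmentation oracle", {
  alphabet <- c("tssB", "tssC", "tssK", x)
  params <- list(c(2, 1), c(3, 2))
  bad <- 0L; total <- 0L
  for (len in 1:5) {
    combos <- as.matrix(do.call(expand.grid,
                                c(rep(list(alphabet), len),
                                  stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(combos))) {
      for (p in params) {
        total <- total + 1L
        if (!scan_agrees(combos[r, ], p[1], p[2])) bad <- bad + 1L
      }
    }
  }
  expect_equal(total, 2L * sum(4^(1:5)))
  expect_equal(bad, 0L)
})

test_that("scan agrees with the oracle on longer random contigs", {
  set.seed(1709)
  cores13 <- t6ss_core_families()
  bad <- 0L
  for (i in 1:150) {
    len <- sample(5:26, 1)
    fams <- sample(c(cores13[1:5], rep(x, 9)), len, replace = TRUE)
    mc <- sample(2:5, 1); mg <- sample(c(1:3, 10), 1)
    if (!scan_agrees(fams, mc, mg)) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("output is invariant to reversing the contig gene order", {
  set.seed(33)
  for (i in 1:25) {
    fams <- sample(c("tssA", "tssB", "tssC", "tssK", rep(x, 6)),
                   sample(6:18, 1), replace = TRUE)
    fwd <- scan_labels(fams)
    rev_cl <- scan_labels(rev(fams))
    expect_equal(nrow(fwd), nrow(rev_cl))
    if (nrow(fwd)) {
      # mirrored spans: gene i maps to n - i + 1
      n <- length(fams)
      fwd_spans <- lapply(seq_len(nrow(fwd)), function(k) {
        idx <- match(fwd$gene_ids[[k]], sprintf("G_%03d", seq_len(n)))
        sort(n - range(idx) + 1)
      })
      rev_spans <- lapply(seq_len(nrow(rev_cl)), function(k) {
        idx <- match(rev_cl$gene_ids[[k]], sprintf("G_%03d", seq_len(n)))
        range(idx)
      })
      expect_setequal(fwd_spans, rev_spans)
    }
  }
})

test_that("raising min_core never adds clusters; raising max_gap only merges", {
  # cluster COUNT is monotone in min_core but not in max_gap: a larger gap
  # allowance can merge two valid clusters into one. The max_gap-monotone
  # quantities are containment (every cluster at a smaller gap lies inside
  # one cluster at a larger gap) and the covered gene set.
  set.seed(91)
  for (i in 1:25) {
    fams <- sample(c("tssA", "tssB", "tssC", "tssK", "tssL", rep(x, 8)),
                   sample(8:22, 1), replace = TRUE)
    for (mg in c(1, 3)) {
      n_by_mc <- vapply(2:6, function(mc)
        nrow(scan_labels(fams, min_core = mc, max_gap = mg)), 0L)
      expect_true(all(diff(n_by_mc) <= 0))
    }
    for (mc in c(2, 3)) {
      gaps <- c(0, 1, 2, 4, 10)
      by_mg <- lapply(gaps, function(mg)
        scan_labels(fams, min_core = mc, max_gap = mg))
      for (j in seq_along(gaps)[-1]) {
        lo <- by_mg[[j - 1]]; hi <- by_mg[[j]]
        cover_lo <- unlist(lo$gene_ids); cover_hi <- unlist(hi$gene_ids)
        expect_true(all(cover_lo %in% cover_hi))
        for (k in seq_len(nrow(lo))) {
          inside <- vapply(seq_len(nrow(hi)), function(h)
            all(lo$gene_ids[[k]] %in% hi$gene_ids[[h]]), TRUE)
          expect_true(any(inside))
        }
      }
    }
  }
})

test_that("clusters on a contig are disjoint, ordered and never share genes", {
  set.seed(55)
  for (i in 1:20) {
    fams <- sample(c("tssA", "tssB", "tssC", rep(x, 4)),
                   sample(10:25, 1), replace = TRUE)
    cl <- scan_labels(fams, min_core = 2, max_gap = 1)
    if (nrow(cl) > 1) {
      ids <- unlist(cl$gene_ids)
      expect_equal(anyDuplicated(ids), 0)
      expect_true(all(diff(cl$span_start) > 0))
    }
  }
})

test_that("truncation is flagged for incomplete clusters near a contig edge", {
  # cluster at the very start of a contig, incomplete -> left-truncated
  cl <- scan_labels(c("tssB", "tssC", "tssK", "tssL", rep(x, 12)))
  expect_equal(cl$truncated, "left")
  # same cluster padded by >= max_gap genes on both sides -> none
  cl2 <- scan_labels(c(rep(x, 10), "tssB", "tssC", "tssK", "tssL", rep(x, 10)))
  expect_equal(cl2$truncated, "none")
  # both edges close -> both
  cl3 <- scan_labels(c("tssB", "tssC", "tssK", "tssL"))
  expect_equal(cl3$truncated, "both")
  # a complete 13-family cluster is never truncation-flagged
  cl4 <- scan_labels(t6ss_core_families())
  expect_equal(cl4$truncated, "none")
  expect_true(cl4$complete)
})

test_that("completeness records name missing families and attribute causes", {
  cl <- scan_labels(c(rep(x, 10), setdiff(t6ss_core_families(),
                                          c("tssD", "tssI")), rep(x, 10)))
  rec <- classify_completeness(cl[1, ])
  expect_false(rec$complete)
  expect_equal(rec$missing, c("tssD", "tssI"))
  expect_equal(rec$cause, "genuinely_absent")

  full <- classify_completeness(scan_labels(t6ss_core_families())[1, ])
  expect_true(full$complete)
  expect_equal(full$missing, character(0))
  expect_true(is.na(full$cause))

  edge <- scan_labels(c(rep(x, 12), t6ss_core_families()[1:9]))
  rec_edge <- classify_completeness(edge[1, ])
  expect_equal(rec_edge$cause, "truncated_assembly")
})

test_that("system labelling follows replicons, with suffixes and conflict handling", {
  g <- toy_genome(c("tssA", "tssB", "tssC", "tssK"))
  fm <- toy_family_map(g, c("tssA", "tssB", "tssC", "tssK"))
  cl <- scan_genome(g, fm)
  lab <- label_known_systems(cl, replicon_map = c(c1 = 2))
  expect_equal(lab$system_label, "T6SS2")
  # two clusters on one replicon get ordinal suffixes
  fams2 <- c("tssA", "tssB", "tssC", "tssK", rep("x", 11),
             "tssA", "tssB", "tssC", "tssL")
  cl2 <- scan_labels(fams2)
  cl2$genome_id <- "G"
  lab2 <- label_known_systems(cl2, replicon_map = c(c1 = 1))
  expect_equal(lab2$system_label, c("T6SS1.1", "T6SS1.2"))
  # replicon vs subtype conflict -> unlabeled with a warning
  st <- data.frame(cluster_id = cl$cluster_id, subtype = "1",
                   stringsAsFactors = FALSE)
  expect_warning(
    lab3 <- label_known_systems(cl, replicon_map = c(c1 = 2), subtypes = st,
                                subtype_system_map = c("1" = "T6SS1")),
    "conflict")
  expect_equal(lab3$system_label, "unlabeled")
})
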