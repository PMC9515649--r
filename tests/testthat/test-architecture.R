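# Sheath domain architecture, fusion identity reports, repertoire calls,
# and the effector screen's threshold behaviour.

dom_row <- function(gene, fam, start, end, score = 100) {
  data.frame(gene_id = gene, family = fam, score = score, evalue = 1e-30,
             ali_start = as.integer(start), ali_end = as.integer(end),
             stringsAsFactors = FALSE)
}

test_that("architecture calls follow the ordered domain-string rules", {
  fus <- scan_architecture(rbind(dom_row("p1", "VipA", 200, 340),
                                 dom_row("p1", "VipA", 440, 580),
                                 dom_row("p1", "VipB", 680, 1110)))
  expect_equal(fus$call, "TssC_L_fusion")
  expect_equal(fus$domain_string, c("VipA", "VipA", "VipB"))

  expect_equal(scan_architecture(dom_row("p2", "VipA", 10, 150))$call,
               "TssB_like")
  expect_equal(scan_architecture(dom_row("p3", "VipB", 50, 480))$call,
               "TssC_like")
  # one VipA plus one VipB is NOT the fusion signature
  expect_equal(scan_architecture(rbind(dom_row("p4", "VipA", 0, 100),
                                       dom_row("p4", "VipB", 150, 500)))$call,
               "other")
  expect_equal(scan_architecture(dom_row("p5", "VipA", 0, 100)[0, ])$call,
               "other")
})

fusion_fixture <- function(idA1 = 0.85, idA2 = 0.25, idB = 0.31) {
  tssB <- random_aa(170); tssC <- random_aa(506)
  vipA <- substr(tssB, 11, 150)
  vipB <- substr(tssC, 51, 480)
  fused <- paste0(random_aa(200), mutate_sequence(vipA, idA1),
                  random_aa(100), mutate_sequence(vipA, idA2),
                  random_aa(100), mutate_sequence(vipB, idB),
                  random_aa(574))
  calls <- list(
    B = scan_architecture(dom_row("gB", "VipA", 10, 150)),
    C = scan_architecture(dom_row("gC", "VipB", 50, 480)),
    L = scan_architecture(rbind(dom_row("gL", "VipA", 200, 340),
                                dom_row("gL", "VipA", 440, 580),
                                dom_row("gL", "VipB", 680, 1110))))
  list(proteins = c(gB = tssB, gC = tssC, gL = fused), calls = calls)
}

test_that("fused domains identical to their partner report identity 1", {
  set.seed(61)
  fx <- fusion_fixture(idA1 = 1.0, idA2 = 0.25, idB = 0.31)
  rep <- domain_identity_report(fx$calls$L, fx$proteins, fx$calls)
  expect_equal(rep$report$identity[rep$report$domain == "VipA"][1], 1.0)
})

test_that("identity reports recover generator-set identities within 0.03", {
  set.seed(62)
  fx <- fusion_fixture(0.85, 0.25, 0.31)
  rep <- domain_identity_report(fx$calls$L, fx$proteins, fx$calls)$report
  vipA <- rep[rep$domain == "VipA", ]
  expect_lt(max(abs(vipA$identity - c(0.85, 0.25))), 0.03)
  vipB <- rep[rep$domain == "VipB", ]
  # exactly one VipB comparison for the 2xVipA + 1xVipB signature
  expect_equal(nrow(vipB), 1)
  expect_lt(abs(vipB$identity - 0.31), 0.03)
  expect_equal(vipB$partner_protein, "gC")
})

test_that("a missing standalone partner omits that comparison with a reason", {
  set.seed(63)
  fx <- fusion_fixture()
  no_b <- fx$calls[c("C", "L")]
  out <- domain_identity_report(fx$calls$L, fx$proteins, no_b)
  expect_equal(sum(out$report$domain == "VipA"), 0)
  expect_equal(sum(out$report$domain == "VipB"), 1)
  expect_length(out$omitted, 2)
  expect_match(out$omitted[1], "no standalone TssB")
})

repertoire_fixture <- function(pattern) {
  set.seed(64)
  fx <- fusion_fixture()
  fams <- c("tssA", "tssB", "tssC", "tssK")
  prots <- c(random_aa(100), fx$proteins[["gB"]], fx$proteins[["gC"]],
             random_aa(120))
  if (pattern == "fusion") {
    fams <- append(fams, "tssC", after = 3)
    prots <- append(prots, fx$proteins[["gL"]], after = 3)
  } else if (pattern == "duplication") {
    fams <- append(fams, "tssC", after = 3)
    prots <- append(prots, mutate_sequence(fx$proteins[["gC"]], 0.35), after = 3)
  }
  g <- toy_genome(fams, proteins = prots)
  fm <- toy_family_map(g, fams)
  cl <- scan_contig(contig_genes(g, "c1"), fm, genome_id = "G")
  sheath_idx <- which(fams %in% c("tssB", "tssC"))
  calls <- lapply(sheath_idx, function(i) {
    p <- prots[i]
    gene <- g$genes$gene_id[i]
    if (nchar(p) == 1684) {
      scan_architecture(rbind(dom_row(gene, "VipA", 200, 340),
                              dom_row(gene, "VipA", 440, 580),
                              dom_row(gene, "VipB", 680, 1110)))
    } else if (nchar(p) == 170) {
      scan_architecture(dom_row(gene, "VipA", 10, 150))
    } else {
      scan_architecture(dom_row(gene, "VipB", 50, 480))
    }
  })
  list(cluster = cl[1, ], calls = calls,
       proteins = stats::setNames(prots, g$genes$gene_id))
}

test_that("repertoires classify as fusion, duplication and standard", {
  fus <- repertoire_fixture("fusion")
  rf <- classify_repertoire(fus$cluster, fus$calls, fus$proteins)
  expect_equal(rf$pattern, "fusion")

  dup <- repertoire_fixture("duplication")
  rd <- classify_repertoire(dup$cluster, dup$calls, dup$proteins)
  expect_equal(rd$pattern, "duplication")
  expect_lt(abs(rd$tssC_pairwise_identity - 0.35), 0.02)

  std <- repertoire_fixture("standard")
  rs <- classify_repertoire(std$cluster, std$calls, std$proteins)
  expect_equal(rs$pattern, "standard")
})

test_that("effector hits require both thresholds, inclusively", {
  set.seed(65)
  db <- stats::setNames(vapply(1:3, function(i) random_aa(200), ""),
                        paste0("eff", 1:3))
  queries <- c(hit = db[["eff1"]],
               weak = mutate_sequence(db[["eff2"]], 0.25),
               decoy = random_aa(180))
  hits <- search_effectors(queries, db)
  expect_true("hit" %in% hits$query_id)
  expect_equal(hits$identity[hits$query_id == "hit"], 1.0)
  # a ~25% mutant's best match sits below the 30% identity rule and is
  # excluded even though its E-value passes easily
  raw <- search_effectors(queries["weak"], db, min_identity = 0,
                          max_evalue = Inf)
  best_weak <- raw[raw$db_protein_id == "eff2", ]
  expect_lt(best_weak$identity, 0.30)
  expect_lt(best_weak$evalue, 1e-6)
  expect_false(any(hits$query_id == "weak"))
  # emitted hits never violate either threshold
  expect_true(all(hits$identity >= 0.30))
  expect_true(all(hits$evalue <= 1e-6))
  expect_error(search_effectors(queries, character(0)), "empty effector")
})

test_that("threshold boundaries are inclusive at exactly the observed values", {
  set.seed(66)
  db <- stats::setNames(vapply(1:2, function(i) random_aa(150), ""),
                        c("d1", "d2"))
  q <- c(q1 = mutate_sequence(db[["d1"]], 0.6))
  base <- search_effectors(q, db, min_identity = 0, max_evalue = Inf)
  obs <- base[base$db_protein_id == "d1", ]
  # thresholds set exactly at the observed values retain the hit ...
  at <- search_effectors(q, db, min_identity = obs$identity,
                         max_evalue = obs$evalue)
  expect_true(nrow(at[at$db_protein_id == "d1", ]) == 1)
  # ... and infinitesimally stricter ones drop it
  above <- search_effectors(q, db, min_identity = obs$identity + 1e-9,
                            max_evalue = obs$evalue)
  expect_equal(nrow(above[above$db_protein_id == "d1", ]), 0)
  below <- search_effectors(q, db, min_identity = obs$identity,
                            max_evalue = obs$evalue * (1 - 1e-9))
  expect_equal(nrow(below[below$db_protein_id == "d1", ]), 0)
})

test_that("50 composition-matched decoys yield zero hits at defaults", {
  set.seed(67)
  panel <- family_reference_panel()
  decoys <- stats::setNames(
    vapply(1:50, function(i) random_protein(200), ""),
    paste0("decoy", 1:50))
  hits <- search_effectors(decoys, panel$effectors)
  expect_equal(nrow(hits), 0)
})
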