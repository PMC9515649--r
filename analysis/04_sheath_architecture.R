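#!/usr/bin/env Rscript
# Sheath-repertoire survey: which clusters carry the standard TssB/TssC
# pair, which carry the long TssC_L fusion (two VipA domains + one VipB),
# and which carry a duplicated tssC; plus the fused-domain identity
# report and the effector screen summary.

library(t6sscan)

run_dir <- "results/run"
if (!dir.exists(run_dir)) stop("run analysis/02_detect_and_type.R first")

rep_tab <- read.delim(file.path(run_dir, "repertoires.tsv"))
cat("sheath repertoire patterns:\n")
print(table(rep_tab$pattern))
dup <- rep_tab[rep_tab$pattern == "duplication", ]
if (nrow(dup)) {
  cat(sprintf("duplicated-tssC pairwise identity: %s%%\n",
              paste(sprintf("%.1f", 100 * dup$tssC_pairwise_identity),
                    collapse = ", ")))
}

eff <- read.delim(file.path(run_dir, "effectors.tsv"))
cat(sprintf("effector screen: %d hits passing identity >= 30%% and E <= 1e-6\n",
            nrow(eff)))
cat(sprintf("  identity range %.0f%%-%.0f%%, worst E-value %.2g\n",
            100 * min(eff$identity), 100 * max(eff$identity),
            max(eff$evalue)))
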