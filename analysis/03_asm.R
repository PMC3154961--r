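#!/usr/bin/env Rscript
# Allele-specific methylation: per-read SNP-CpG tables, Fisher tests with
# Storey q-values at 5% FDR, per-SNP aggregation, the mean allelic
# difference at non-disrupting events, and cross-sample concordance between
# the two sons (same planted effects, independent reads).

library(asmfam)
res <- readRDS("results/pipeline_bundle.rds")
dir.create("results/asm", showWarnings = FALSE, recursive = TRUE)

for (id in names(res$asm)) {
  p <- res$asm[[id]]$pairs
  sig <- p[p$significant, ]
  cat(sprintf("%s: %d pairs, %d testable, %d significant (%d CpG-disrupting)\n",
              id, nrow(p), sum(p$testable), nrow(sig),
              sum(sig$cpg_disrupting)))
  write.table(p, file.path("results/asm", paste0(id, "_pairs.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

all_sig <- do.call(rbind, lapply(res$asm, function(es) {
  es$pairs[es$pairs$significant & !es$pairs$cpg_disrupting, , drop = FALSE]
}))
cat(sprintf("\nmean |delta| at significant non-disrupting events: %.1f points (n = %d)\n",
            mean(abs(all_sig$delta)), nrow(all_sig)))

cmp <- compare_event_sets(res$asm$E, res$asm$F)
cat(sprintf("son E vs son F: %d significant in E, %d testable in F, overlap %.1f%%, direction consistency %.1f%%\n",
            cmp$n_significant_a, cmp$n_testable_in_b, 100 * cmp$overlap,
            100 * cmp$direction_consistency))

agg <- aggregate_asm_events(res$asm$C)
cat(sprintf("individual C: %d SNPs with pairs, %d with significant ASM\n",
            nrow(agg), sum(agg$n_significant > 0)))
write.table(agg, "results/asm/C_per_snp.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
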