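#!/usr/bin/env Rscript
# Bisulfite alignment and calling, audited against simulation truth: fraction
# of reads aligned and placed correctly, CpG methylation calls at >= 14x, and
# SNP/genotype calls compared with the planted variants.

library(asmfam)
res <- readRDS("results/pipeline_bundle.rds")
dir.create("results/calls", showWarnings = FALSE, recursive = TRUE)

for (id in names(res$alignments)) {
  aln <- res$alignments[[id]]
  truth <- res$reads[[id]]$truth
  m <- match(aln$read_id, truth$id)
  placed <- mean(aln$chrom == truth$chrom[m] & aln$start == truth$start[m] &
                   aln$strand == truth$strand[m])
  cat(sprintf("%s: %d/%d reads aligned (%.1f%%), %.2f%% placed correctly\n",
              id, nrow(aln), nrow(truth), 100 * nrow(aln) / nrow(truth),
              100 * placed))
}

cat(sprintf("\nCpG calls (>=14x) per individual: %s\n",
            paste(sprintf("%s=%d", names(res$cpg_calls),
                          vapply(res$cpg_calls, nrow, 0L)), collapse = " ")))

planted <- paste(res$hs$snps$chrom, res$hs$snps$pos)
for (id in names(res$snp_calls)) {
  s <- res$snp_calls[[id]]
  s <- s[s$class == "callable", ]
  tp <- sum(paste(s$chrom, s$pos) %in% planted)
  cat(sprintf("%s: %d callable SNPs, %d at planted positions, %d heterozygous\n",
              id, nrow(s), tp, sum(s$het)))
  write.table(s, file.path("results/calls", paste0(id, "_snps.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(res$cpg_calls[[id]],
              file.path("results/calls", paste0(id, "_methylation.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
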