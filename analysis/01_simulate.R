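#!/usr/bin/env Rscript
# Simulate the study cohort: a ~150 kb reference, the three-generation family
# (six assayed members) plus two unrelated individuals, 60 SNPs of which a
# quarter destroy a CpG, genotype and imprinted methylation effects at the
# default 59.8-point mean allelic difference, and 50x RRBS reads per
# individual. Writes FASTA/FASTQ/PED plus the truth tables downstream stages
# are audited against. Truth never travels inside the FASTQ.

library(asmfam)
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- run_config(seed = 20260929)
res <- run_pipeline(cfg, keep_reads = TRUE)
saveRDS(res, "results/pipeline_bundle.rds")

write_reference_fasta(res$ref, file.path(out, "reference.fasta"))
write_pedigree(res$ped, file.path(out, "pedigree.ped"))
for (id in names(res$reads)) {
  write_fastq(res$reads[[id]]$reads, file.path(out, paste0(id, ".fastq")))
  write.table(res$reads[[id]]$truth, file.path(out, paste0(id, ".truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(res$hs$snps, file.path(out, "snp_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$hs$truth, file.path(out, "effect_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("reference: %d bp, %d CpGs, %d MspI sites, %d assayable fragments\n",
            sum(nchar(res$ref$chromosomes)), nrow(res$ref$cpg),
            nrow(res$ref$msp), nrow(msp_fragments(res$ref))))
cat(sprintf("planted SNPs: %d (%d CpG-disrupting)\n", nrow(res$hs$snps),
            sum(res$hs$snps$cpg_disrupting)))
print(table(res$hs$truth$class[!duplicated(res$hs$truth$snp_id)]))
cat(sprintf("reads per individual: %s\n",
            paste(sprintf("%s=%d", names(res$reads),
                          vapply(res$reads, function(x) nrow(x$reads), 0L)),
                  collapse = " ")))
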