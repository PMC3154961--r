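#!/usr/bin/env Rscript
# Linear genotype->methylation models per CpG-SNP pair (sd >= 25 filter,
# ANOVA F, q < 0.05), held-out prediction of methylation in the two unrelated
# individuals, and average-linkage clustering of all assayed individuals on
# the most variable CpGs.

library(asmfam)
res <- readRDS("results/pipeline_bundle.rds")
dir.create("results/model", showWarnings = FALSE, recursive = TRUE)

fits <- res$fits
cat(sprintf("fitted pairs: %d, significant at 5%% FDR: %d\n",
            nrow(fits), sum(fits$significant)))
write.table(as.data.frame(fits), "results/model/fits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

for (id in names(res$predictions)) {
  p <- res$predictions[[id]]
  if (p$defined) {
    cat(sprintf("held-out %s: R^2 = %.2f over %d pairs\n", id, p$r2,
                nrow(p$table)))
  } else {
    cat(sprintf("held-out %s: too few predictable pairs\n", id))
  }
}

if (!is.null(res$clustering)) {
  writeLines(res$clustering$newick, "results/model/dendrogram.nwk")
  cat("dendrogram:", res$clustering$newick, "\n")
  co <- as.matrix(stats::cophenetic(res$clustering$hclust))
  fam <- intersect(res$family, rownames(co))
  unrel <- intersect(res$unrelated, rownames(co))
  if (length(fam) > 1 && length(unrel)) {
    within <- mean(co[fam, fam][upper.tri(co[fam, fam])])
    between <- mean(co[fam, unrel, drop = FALSE])
    cat(sprintf("mean cophenetic distance within family %.1f vs family-to-unrelated %.1f\n",
                within, between))
  }
}
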