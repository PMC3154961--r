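#' Fit per-pair linear models of methylation on genotype
#'
#' For each CpG-SNP pair, regresses percent methylation on the genotype
#' dosage code (0 = homozygous reference, 0.5 = heterozygous, 1 = homozygous
#' variant) across individuals by ordinary least squares, with the model
#' premise that a heterozygote sits halfway between the two homozygotes. A
#' pair is fitted only if the CpG's methylation standard deviation across
#' individuals is at least `sd_min` percentage points and the SNP shows at
#' least two distinct genotype codes. ANOVA provides the F-test p-value of
#' each model; q-values are computed across all fitted pairs and models with
#' q below `fdr` are significant.
#'
#' @param meth methylation percent matrix (CpGs x individuals, "chrom:pos"
#'   rownames) from [methylation_matrix()].
#' @param geno genotype matrix (SNPs x individuals) from [genotype_matrix()].
#' @param pairs data.frame with columns `cpg` and `snp` (rowname keys);
#'   NULL pairs every CpG with every same-chromosome SNP within
#'   `max_distance` bp.
#' @param sd_min minimum methylation standard deviation (default 25).
#' @param fdr FDR threshold for significance (default 0.05).
#' @param q_method "storey" or "BH" (see [storey_qvalue()]).
#' @param max_distance pairing window when `pairs` is derived (default 35,
#'   one read length).
#' @return data.frame of class `genotype_model_fits`: cpg, snp, n, slope,
#'   intercept, sd_meth, p, q, significant.
#' @export
fit_genotype_models <- function(meth, geno, pairs = NULL, sd_min = 25,
                                fdr = 0.05, q_method = c("storey", "BH"),
                                max_distance = 35L) {
  q_method <- match.arg(q_method)
  if (is.null(pairs)) pairs <- derive_pairs(rownames(meth), rownames(geno), max_distance)
  shared <- intersect(colnames(meth), colnames(geno))
  if (length(shared) < 3) stopf("need at least 3 shared individuals")
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    cpg <- pairs$cpg[i]; snp <- pairs$snp[i]
    if (!(cpg %in% rownames(meth)) || !(snp %in% rownames(geno))) next
    y <- meth[cpg, shared]
    g <- geno[snp, shared]
    ok <- !is.na(y) & !is.na(g)
    if (sum(ok) < 3) next
    y <- y[ok]; g <- g[ok]
    sd_y <- sd(y)
    if (is.na(sd_y) || sd_y < sd_min) next
    if (length(unique(g)) < 2) next
    fit <- lm(y ~ g)
    an <- anova(fit)
    rows[[length(rows) + 1L]] <- data.frame(
      cpg = cpg, snp = snp, n = sum(ok),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      sd_meth = sd_y, p = an[["Pr(>F)"]][1])
  }
  out <- do.call(rbind, rows) %||%
    data.frame(cpg = character(0), snp = character(0), n = integer(0),
               slope = numeric(0), intercept = numeric(0),
               sd_meth = numeric(0), p = numeric(0))
  if (nrow(out)) {
    out$q <- if (q_method == "storey") storey_qvalue(out$p) else p.adjust(out$p, "BH")
    out$significant <- out$q < fdr
  } else {
    out$q <- numeric(0)
    out$significant <- logical(0)
  }
  rownames(out) <- NULL
  class(out) <- c("genotype_model_fits", "data.frame")
  out
}

derive_pairs <- function(cpg_keys, snp_keys, max_distance) {
  split_keys <- function(k) {
    parts <- strsplit(k, ":", fixed = TRUE)
    data.frame(key = k, chrom = vapply(parts, `[`, "", 1),
               pos = as.integer(vapply(parts, `[`, "", 2)))
  }
  cp <- split_keys(cpg_keys)
  sp <- split_keys(snp_keys)
  rows <- list()
  for (cn in intersect(unique(cp$chrom), unique(sp$chrom))) {
    c1 <- cp[cp$chrom == cn, ]
    s1 <- sp[sp$chrom == cn, ]
    for (i in seq_len(nrow(s1))) {
      near <- abs(c1$pos - s1$pos[i]) <= max_distance
      if (any(near)) {
        rows[[length(rows) + 1L]] <- data.frame(cpg = c1$key[near],
                                                snp = s1$key[i])
      }
    }
  }
  do.call(rbind, rows) %||% data.frame(cpg = character(0), snp = character(0))
}

#' Predict methylation in a held-out individual from fitted models
#'
#' Applies `intercept + slope * genotype` for every fitted pair where the
#' individual has a genotype call, compares with the observed percent
#' methylation, and reports the squared Pearson correlation pooled over all
#' pairs.
#'
#' @param fits a `genotype_model_fits` table.
#' @param genotypes named numeric vector (SNP key -> genotype code) for the
#'   target individual.
#' @param observed named numeric vector (CpG key -> observed percent
#'   methylation).
#' @param use "significant" (default) restricts to significant models; "all"
#'   uses every fitted pair.
#' @return list with `table` (cpg, snp, predicted, observed) and `r2`;
#'   `r2` is NA with `defined = FALSE` when fewer than 2 pairs overlap.
#' @export
predict_methylation <- function(fits, genotypes, observed,
                                use = c("significant", "all")) {
  use <- match.arg(use)
  f <- if (use == "significant") fits[fits$significant, , drop = FALSE] else fits
  g <- genotypes[f$snp]
  o <- observed[f$cpg]
  ok <- !is.na(g) & !is.na(o)
  tab <- data.frame(cpg = f$cpg[ok], snp = f$snp[ok],
                    predicted = f$intercept[ok] + f$slope[ok] * g[ok],
                    observed = unname(o[ok]))
  if (nrow(tab) < 2 || sd(tab$predicted) == 0 || sd(tab$observed) == 0) {
    return(list(table = tab, r2 = NA_real_, defined = FALSE))
  }
  list(table = tab, r2 = cor(tab$predicted, tab$observed)^2, defined = TRUE)
}

#' Hierarchical clustering of individuals on the most variable CpGs
#'
#' Ranks CpGs by cross-individual variance of percent methylation, keeps the
#' top `top_n`, and clusters individuals by average-linkage hierarchical
#' clustering of Euclidean distances. CpGs with missing values are dropped
#' before ranking.
#'
#' @param meth methylation percent matrix (CpGs x individuals).
#' @param top_n number of most-varying CpGs to use (default 237).
#' @return list with `hclust` (the dendrogram), `newick` (serialised tree
#'   with branch lengths), and `cpgs` (the CpG keys used). All merge heights
#'   zero raises a warning (constant matrix).
#' @export
cluster_individuals <- function(meth, top_n = 237L) {
  if (ncol(meth) < 2) stopf("need at least 2 individuals to cluster")
  complete <- meth[stats::complete.cases(meth), , drop = FALSE]
  if (!nrow(complete)) stopf("no CpGs with complete data")
  v <- apply(complete, 1, var)
  keep <- head(order(v, decreasing = TRUE), min(top_n, nrow(complete)))
  sub <- complete[keep, , drop = FALSE]
  hc <- hclust(dist(t(sub)), method = "average")
  if (all(hc$height == 0)) warning("all merge heights are zero (constant methylation matrix)")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, newick = nwk, cpgs = rownames(sub))
}
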