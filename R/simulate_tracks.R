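#' Simulate per-gene allelic expression counts linked to planted effects
#'
#' Emits a table of allele-1/allele-2 RNA read counts per annotated gene.
#' Genes whose TSS lies within `tss_window` bp of a planted effect SNP
#' (genotype, imprinted or CpG-disrupting class) are allele-biased with
#' probability `p_ase_linked`; other genes with probability `p_ase_background`.
#' Biased genes draw their allele-1 fraction uniformly from `bias_range`
#' (randomly oriented); unbiased genes are balanced. Total depth per gene is
#' negative binomial, so a realistic share of genes falls below the 25-read
#' testability cutoff.
#'
#' @param hs a `haplotype_set` with effects assigned.
#' @param tss_window linkage window around the TSS in bp (default 5000).
#' @param p_ase_linked probability of allelic bias for effect-linked genes.
#' @param p_ase_background probability of allelic bias for other genes.
#' @param bias_range range of the major-allele expression fraction.
#' @param mean_depth mean total allele-informative reads per gene.
#' @param seed integer seed.
#' @return list with `counts` (gene, a1, a2) and `truth` (gene, linked,
#'   is_ase, bias).
#' @export
simulate_ase_counts <- function(hs, tss_window = 5000L,
                                p_ase_linked = 0.6,
                                p_ase_background = 0.08,
                                bias_range = c(0.75, 0.95),
                                mean_depth = 120,
                                seed = 1L) {
  gt <- hs$ref$genes$genes
  if (is.null(gt) || nrow(gt) == 0) {
    return(list(counts = data.frame(gene = character(0), a1 = integer(0),
                                    a2 = integer(0)),
                truth = data.frame(gene = character(0), linked = logical(0),
                                   is_ase = logical(0), bias = numeric(0))))
  }
  eff <- hs$truth[hs$truth$class != "null", , drop = FALSE]
  with_seed(seed, {
    linked <- vapply(seq_len(nrow(gt)), function(i) {
      e <- eff[eff$chrom == gt$chrom[i], , drop = FALSE]
      nrow(e) > 0 && any(abs(e$snp_pos - gt$tss[i]) <= tss_window)
    }, logical(1))
    is_ase <- runif(nrow(gt)) < ifelse(linked, p_ase_linked, p_ase_background)
    bias <- ifelse(is_ase, runif(nrow(gt), bias_range[1], bias_range[2]), 0.5)
    flip <- runif(nrow(gt)) < 0.5
    frac1 <- ifelse(flip, 1 - bias, bias)
    total <- stats::rnbinom(nrow(gt), mu = mean_depth, size = 2)
    a1 <- rbinom(nrow(gt), total, frac1)
    list(counts = data.frame(gene = gt$gene, a1 = a1, a2 = total - a1),
         truth = data.frame(gene = gt$gene, linked = linked, is_ase = is_ase,
                            bias = bias))
  })
}

#' Simulate a conservation-like score track
#'
#' Per-position scores drawn from a standard normal baseline, elevated inside
#' gene bodies (functional constraint) and optionally shifted at supplied
#' positions (e.g. planted methylation-effect SNPs in weakly constrained
#' territory).
#'
#' @param ref a `synthetic_reference`.
#' @param positions data.frame with chrom, pos: positions to score.
#' @param shifted_positions optional data.frame with chrom, pos whose scores
#'   receive `shift`.
#' @param gene_bonus additive score inside gene bodies (default 1.2).
#' @param shift additive score at `shifted_positions` (default -0.8).
#' @param seed integer seed.
#' @return data.frame: chrom, pos, score.
#' @export
simulate_conservation_scores <- function(ref, positions,
                                         shifted_positions = NULL,
                                         gene_bonus = 1.2, shift = -0.8,
                                         seed = 1L) {
  with_seed(seed, {
    out <- data.frame(chrom = positions$chrom, pos = positions$pos)
    out$score <- rnorm(nrow(out))
    gt <- ref$genes$genes
    if (!is.null(gt) && nrow(gt)) {
      out$score <- out$score + gene_bonus *
        in_intervals(out, data.frame(chrom = gt$chrom, start = gt$start,
                                     end = gt$end))
    }
    if (!is.null(shifted_positions) && nrow(shifted_positions)) {
      hit <- pos_key(out$chrom, out$pos) %in%
        pos_key(shifted_positions$chrom, shifted_positions$pos)
      out$score[hit] <- out$score[hit] + shift
    }
    out
  })
}
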