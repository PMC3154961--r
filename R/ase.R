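#' Test allele-specific expression from per-gene allelic read counts
#'
#' Two-sided exact binomial test of the allele-1 read count against an equal
#' (0.5) expectation per gene, with Benjamini-Hochberg adjustment across all
#' tested genes. Genes with fewer than `min_reads` total allele-informative
#' reads are excluded: at 25 reads an 80% bias toward one allele is the
#' smallest effect detectable at p < 0.05.
#'
#' @param counts data.frame with columns gene, a1, a2 (reads supporting each
#'   allele/haplotype).
#' @param min_reads minimum total reads to test a gene (default 25,
#'   inclusive).
#' @param fdr FDR threshold for the significant flag (default 0.05).
#' @param method "minlik" (default; sums all outcomes no more likely than the
#'   observed one, as `binom.test` does) or "double" (twice the smaller tail,
#'   capped at 1).
#' @return data.frame: gene, a1, a2, total, major_fraction, tested, p, padj,
#'   significant.
#' @export
test_ase <- function(counts, min_reads = 25L, fdr = 0.05,
                     method = c("minlik", "double")) {
  method <- match.arg(method)
  out <- data.frame(gene = counts$gene, a1 = counts$a1, a2 = counts$a2)
  out$total <- out$a1 + out$a2
  if (any(out$a1 < 0 | out$a2 < 0)) stopf("allelic counts must be non-negative")
  out$major_fraction <- ifelse(out$total > 0,
                               pmax(out$a1, out$a2) / out$total, NA_real_)
  out$tested <- out$total >= min_reads
  out$p <- NA_real_
  for (i in which(out$tested)) {
    out$p[i] <- binom_two_sided(out$a1[i], out$total[i], 0.5, method)
  }
  out$padj <- NA_real_
  out$padj[out$tested] <- p.adjust(out$p[out$tested], "BH")
  out$significant <- !is.na(out$padj) & out$padj < fdr
  out
}

#' Two-sided exact binomial p-value
#'
#' @param x successes.
#' @param n trials.
#' @param p0 null success probability.
#' @param method "minlik" (sum of outcome probabilities no larger than the
#'   observed outcome's, the `binom.test` convention) or "double" (twice the
#'   smaller one-sided tail, capped at 1).
#' @return p-value.
#' @export
binom_two_sided <- function(x, n, p0, method = c("minlik", "double")) {
  method <- match.arg(method)
  if (method == "minlik") {
    binom.test(x, n, p0)$p.value
  } else {
    lower <- stats::pbinom(x, n, p0)
    upper <- stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
    min(1, 2 * min(lower, upper))
  }
}

#' Hypergeometric enrichment of a gene subset
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing `k` successes
#' in a sample of `n`, given `K` successes in a population of `N`, with fold
#' enrichment (k/n)/(K/N).
#'
#' @param N population size.
#' @param K successes in the population.
#' @param n sample size.
#' @param k observed successes in the sample.
#' @return list with p, fold, and the echoed counts.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (k > min(n, K) || K > N || n > N || any(c(N, K, n, k) < 0)) {
    stopf("invalid hypergeometric counts")
  }
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  list(p = p, fold = fold, N = N, K = K, n = n, k = k)
}

#' Enrichment of allele-specific expression among ASM-proximal genes
#'
#' Population: all ASE-tested genes. Successes: ASE-significant genes.
#' Sample: tested genes with an ASM event (SNP position) within `tss_window`
#' bp of their transcription start site; each gene counts once regardless of
#' how many events sit near it. Reports the upper-tail hypergeometric
#' probability and fold enrichment.
#'
#' @param ase results from [test_ase()].
#' @param asm_events data.frame with chrom and snp_pos of significant ASM
#'   events (e.g. the significant pairs of an `asm_event_set`).
#' @param genes data.frame with gene, chrom, tss.
#' @param tss_window window around the TSS in bp (default 5000, inclusive).
#' @return list as [hypergeom_enrichment()] plus the sample gene ids;
#'   `defined = FALSE` when no tested gene is ASM-proximal.
#' @export
asm_ase_enrichment <- function(ase, asm_events, genes, tss_window = 5000L) {
  tested <- ase[ase$tested, , drop = FALSE]
  N <- nrow(tested)
  K <- sum(tested$significant)
  ginfo <- genes[match(tested$gene, genes$gene), , drop = FALSE]
  proximal <- vapply(seq_len(nrow(tested)), function(i) {
    ev <- asm_events[asm_events$chrom == ginfo$chrom[i], , drop = FALSE]
    nrow(ev) > 0 && any(abs(ev$snp_pos - ginfo$tss[i]) <= tss_window)
  }, logical(1))
  n <- sum(proximal)
  if (n == 0) {
    return(list(p = NA_real_, fold = NA_real_, N = N, K = K, n = 0L, k = 0L,
                sample_genes = character(0), defined = FALSE))
  }
  k <- sum(proximal & tested$significant)
  res <- hypergeom_enrichment(N, K, n, k)
  res$sample_genes <- tested$gene[proximal]
  res$defined <- TRUE
  res
}

#' Validate allelic expression bias against a genomic-DNA background
#'
#' Two-sided binomial test of the cDNA allele-1 count with success
#' probability equal to the allele-1 fraction observed in genomic DNA, so
#' that amplification or alignment bias shared by both templates cancels.
#'
#' @param cdna,gdna length-2 numeric vectors of allele-1 and allele-2 read
#'   counts in cDNA and genomic DNA.
#' @param method two-sided method, see [binom_two_sided()].
#' @return list with p, direction ("allele1" | "allele2" | "none": which
#'   allele is over-represented relative to the background), cdna_fraction,
#'   background_fraction, degenerate (TRUE when the gDNA fraction is 0 or 1).
#' @export
validate_allele_bias <- function(cdna, gdna, method = c("minlik", "double")) {
  method <- match.arg(method)
  if (sum(cdna) <= 0 || sum(gdna) <= 0) stopf("count totals must be positive")
  p0 <- gdna[1] / sum(gdna)
  if (p0 %in% c(0, 1)) {
    return(list(p = NA_real_, direction = NA_character_,
                cdna_fraction = cdna[1] / sum(cdna),
                background_fraction = p0, degenerate = TRUE))
  }
  fr <- cdna[1] / sum(cdna)
  list(p = binom_two_sided(cdna[1], sum(cdna), p0, method),
       direction = if (fr > p0) "allele1" else if (fr < p0) "allele2" else "none",
       cdna_fraction = fr, background_fraction = p0, degenerate = FALSE)
}
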