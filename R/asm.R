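#' Per-read SNP-CpG contingency tables
#'
#' For every heterozygous callable SNP and every passing CpG close enough to
#' share a read, counts reads that cover both positions, crossing the allele
#' the read carries with the methylation state it shows. Each read contributes
#' exactly once per pair; reads ambiguous for allele or methylation are
#' dropped. For a SNP that destroys the CpG being tested, variant-allele reads
#' are counted as unmethylated (there is no CpG to methylate on that allele)
#' and the pair is flagged `cpg_disrupting`.
#'
#' @param aln alignments from [convert_and_align()].
#' @param snps SNP calls from [call_snps()]; only heterozygous callable SNPs
#'   are paired.
#' @param cpgs methylation calls from [call_cpg_methylation()].
#' @param read_length read length; SNP and CpG must be within one read.
#' @return data.frame: chrom, snp_pos, ref, var, cpg_pos, ref_meth,
#'   ref_unmeth, var_meth, var_unmeth, cpg_disrupting.
#' @export
build_snp_cpg_tables <- function(aln, snps, cpgs, read_length = 36L) {
  empty <- data.frame(chrom = character(0), snp_pos = integer(0),
                      ref = character(0), var = character(0),
                      cpg_pos = integer(0), ref_meth = integer(0),
                      ref_unmeth = integer(0), var_meth = integer(0),
                      var_unmeth = integer(0), cpg_disrupting = logical(0))
  snps <- snps[snps$het & snps$class == "callable", , drop = FALSE]
  if (!nrow(snps) || !nrow(cpgs) || !nrow(aln)) return(empty)

  rows <- list()
  for (cn in unique(snps$chrom)) {
    s_chr <- snps[snps$chrom == cn, , drop = FALSE]
    c_chr <- cpgs[cpgs$chrom == cn, , drop = FALSE]
    a_chr <- aln[aln$chrom == cn, , drop = FALSE]
    if (!nrow(c_chr) || !nrow(a_chr)) next
    # sort by start so reads covering an interval are a contiguous slice
    ord <- order(a_chr$start)
    starts <- as.double(a_chr$start[ord])
    strand <- a_chr$strand[ord]
    M <- str_matrix(a_chr$fwd_seq[ord], read_length)

    # enumerate candidate pairs, then locate their read slices in one batch
    pl <- list()
    for (i in seq_len(nrow(s_chr))) {
      near <- c_chr$pos[abs(c_chr$pos - s_chr$pos[i]) <= read_length - 1L]
      if (length(near)) pl[[i]] <- data.frame(i = i, cp = near)
    }
    if (!length(pl)) next
    pd <- do.call(rbind, pl)
    sp_all <- s_chr$pos[pd$i]
    # superset slice bounds (inclusive of both strand cases); the exact cover
    # check happens per read inside pair_counts
    lo <- pmax(sp_all, pd$cp) - read_length + 1L
    hi <- pmin(sp_all, pd$cp + 1L)
    fi <- findInterval(c(lo - 0.5, hi + 0.5), starts)
    from <- fi[seq_len(nrow(pd))] + 1L
    to <- fi[nrow(pd) + seq_len(nrow(pd))]
    for (r in seq_len(nrow(pd))) {
      if (to[r] < from[r]) next
      i <- pd$i[r]; sp <- sp_all[r]; cp <- pd$cp[r]
      disrupting <- s_chr$cpg_disrupting[i] && sp %in% c(cp, cp + 1L)
      sl <- from[r]:to[r]
      counts <- pair_counts(strand[sl], starts[sl],
                            M[sl, , drop = FALSE], sp,
                            s_chr$ref[i], s_chr$var[i], cp,
                            disrupting, read_length)
      if (is.null(counts)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, snp_pos = sp, ref = s_chr$ref[i], var = s_chr$var[i],
        cpg_pos = cp, ref_meth = counts[1], ref_unmeth = counts[2],
        var_meth = counts[3], var_unmeth = counts[4],
        cpg_disrupting = disrupting)
    }
  }
  out <- do.call(rbind, rows) %||% empty
  rownames(out) <- NULL
  out
}

pair_counts <- function(strand, start, M, snp_pos, ref, var, cpg_pos,
                        disrupting, read_length) {
  # methylation evidence position depends on strand: C itself on forward
  # reads, the paired G on reverse reads
  meth_pos <- ifelse(strand == "+", cpg_pos, cpg_pos + 1L)
  end <- start + read_length - 1L
  cover <- start <= pmin(snp_pos, meth_pos) & end >= pmax(snp_pos, meth_pos)
  if (!any(cover)) return(NULL)
  idx <- which(cover)
  snp_base <- M[cbind(idx, snp_pos - start[idx] + 1L)]
  allele <- assign_allele(snp_base, strand[idx], ref, var)
  meth_base <- M[cbind(idx, meth_pos[idx] - start[idx] + 1L)]
  meth <- ifelse(strand[idx] == "+",
                 ifelse(meth_base == "C", TRUE,
                        ifelse(meth_base == "T", FALSE, NA)),
                 ifelse(meth_base == "G", TRUE,
                        ifelse(meth_base == "A", FALSE, NA)))
  if (disrupting) meth[allele == var & !is.na(allele)] <- FALSE
  ok <- !is.na(allele) & !is.na(meth)
  if (!any(ok)) return(NULL)
  c(sum(allele[ok] == ref & meth[ok]), sum(allele[ok] == ref & !meth[ok]),
    sum(allele[ok] == var & meth[ok]), sum(allele[ok] == var & !meth[ok]))
}

#' Test SNP-CpG pairs for allele-specific methylation
#'
#' Two-sided Fisher's exact test on each 2x2 allele-by-methylation table,
#' with q-values computed across all testable pairs and events called at
#' q < `fdr`. Pairs with an empty margin are untestable and reported with
#' p = 1; pairs with fewer than `min_per_allele` reads on either allele are
#' excluded from testing.
#'
#' @param pairs table from [build_snp_cpg_tables()].
#' @param fdr false discovery rate for event calling (default 0.05).
#' @param q_method "storey" (default) or "BH"; Storey's estimate falls back
#'   to BH (pi0 = 1) when fewer than 100 pairs are tested.
#' @param min_per_allele minimum reads per allele for testability (default 5).
#' @param sample_id optional label carried into the result.
#' @return an `asm_event_set`: list with `pairs` (input plus pct_ref, pct_var,
#'   delta = pct_ref - pct_var, testable, p, q, significant, more_methylated)
#'   and the calling parameters.
#' @export
test_asm <- function(pairs, fdr = 0.05, q_method = c("storey", "BH"),
                     min_per_allele = 5L, sample_id = NA_character_) {
  q_method <- match.arg(q_method)
  p <- pairs
  n <- nrow(p)
  p$ref_total <- p$ref_meth + p$ref_unmeth
  p$var_total <- p$var_meth + p$var_unmeth
  p$pct_ref <- ifelse(p$ref_total > 0, 100 * p$ref_meth / p$ref_total, NA_real_)
  p$pct_var <- ifelse(p$var_total > 0, 100 * p$var_meth / p$var_total, NA_real_)
  p$delta <- p$pct_ref - p$pct_var
  meth_margin <- p$ref_meth + p$var_meth
  unmeth_margin <- p$ref_unmeth + p$var_unmeth
  p$testable <- p$ref_total >= min_per_allele & p$var_total >= min_per_allele &
    meth_margin > 0 & unmeth_margin > 0
  p$p <- rep(NA_real_, n)
  p$p[!p$testable] <- 1
  for (i in which(p$testable)) {
    tab <- matrix(c(p$ref_meth[i], p$ref_unmeth[i],
                    p$var_meth[i], p$var_unmeth[i]), 2, byrow = TRUE)
    p$p[i] <- fisher.test(tab)$p.value
  }
  p$q <- NA_real_
  if (any(p$testable)) {
    p$q[p$testable] <- if (q_method == "storey") {
      storey_qvalue(p$p[p$testable])
    } else {
      p.adjust(p$p[p$testable], "BH")
    }
  }
  p$significant <- !is.na(p$q) & p$q < fdr & p$testable
  p$more_methylated <- ifelse(is.na(p$delta) | p$delta == 0, NA_character_,
                              ifelse(p$delta > 0, "ref", "var"))
  out <- list(pairs = p, fdr = fdr, q_method = q_method,
              min_per_allele = min_per_allele, sample_id = sample_id)
  class(out) <- "asm_event_set"
  out
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 from the p-value distribution on a
#' lambda grid (0.05-0.9) with a cubic smoothing spline evaluated at the
#' largest lambda, then scales Benjamini-Hochberg adjusted p-values by pi0
#' and enforces monotonicity. With fewer than `min_m` p-values the pi0
#' estimate is unstable and the function falls back to pi0 = 1 (plain BH).
#'
#' @param p numeric vector of p-values.
#' @param lambda tuning grid for the pi0 estimate.
#' @param min_m minimum number of p-values to attempt pi0 estimation.
#' @return q-values in the order of `p`.
#' @export
storey_qvalue <- function(p, lambda = seq(0.05, 0.9, by = 0.05), min_m = 100L) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  pi0 <- 1
  if (m >= min_m) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      est <- predict(fit, x = max(lambda))$y
      if (is.finite(est) && est > 0) pi0 <- min(est, 1)
    }
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(cummin(q), 1)
  q[ro]
}

#' Compare ASM event sets between two samples
#'
#' Overlap is computed over events significant in `a` that are testable in
#' `b` (both alleles covered at `b`'s per-allele threshold): the fraction
#' also significant in `b`; among shared significant events, direction
#' consistency is the fraction with the same more-methylated allele, and the
#' allele-switch fraction is its complement.
#'
#' @param a,b `asm_event_set` objects over shared coordinates.
#' @return list with n_significant_a, n_testable_in_b, n_shared, overlap,
#'   direction_consistency, allele_switch (fractions NA when the testable
#'   intersection is empty, with `defined = FALSE`).
#' @export
compare_event_sets <- function(a, b) {
  pa <- a$pairs[a$pairs$significant, , drop = FALSE]
  pb <- b$pairs
  ka <- pair_key(pa$chrom, pa$snp_pos, pa$cpg_pos)
  kb <- pair_key(pb$chrom, pb$snp_pos, pb$cpg_pos)
  m <- match(ka, kb)
  testable_b <- !is.na(m) & pb$testable[m]
  n_testable <- sum(testable_b)
  if (n_testable == 0) {
    return(list(n_significant_a = nrow(pa), n_testable_in_b = 0L,
                n_shared = 0L, overlap = NA_real_,
                direction_consistency = NA_real_, allele_switch = NA_real_,
                defined = FALSE))
  }
  shared <- testable_b & pb$significant[m]
  n_shared <- sum(shared)
  consistent <- pa$more_methylated[shared] == pb$more_methylated[m[shared]]
  list(n_significant_a = nrow(pa),
       n_testable_in_b = n_testable,
       n_shared = n_shared,
       overlap = n_shared / n_testable,
       direction_consistency = if (n_shared) mean(consistent) else NA_real_,
       allele_switch = if (n_shared) 1 - mean(consistent) else NA_real_,
       defined = TRUE)
}

#' Per-SNP aggregation of ASM events
#'
#' Summarises significant pairs per SNP: how many CpGs each SNP is linked to,
#' and for CpG-disrupting SNPs whether another (non-disrupted) CpG within one
#' read length also shows allele specificity.
#'
#' @param es an `asm_event_set`.
#' @param read_length neighbourhood for the nearby-CpG statistic.
#' @return data.frame per SNP: chrom, snp_pos, n_pairs, n_significant,
#'   cpg_disrupting, nearby_other_asm.
#' @export
aggregate_asm_events <- function(es, read_length = 36L) {
  p <- es$pairs
  if (!nrow(p)) {
    return(data.frame(chrom = character(0), snp_pos = integer(0),
                      n_pairs = integer(0), n_significant = integer(0),
                      cpg_disrupting = logical(0),
                      nearby_other_asm = logical(0)))
  }
  key <- pos_key(p$chrom, p$snp_pos)
  split_idx <- split(seq_len(nrow(p)), key)
  out <- do.call(rbind, lapply(split_idx, function(ix) {
    x <- p[ix, , drop = FALSE]
    disr <- any(x$cpg_disrupting)
    other_sig <- x$significant & !x$cpg_disrupting &
      abs(x$cpg_pos - x$snp_pos) <= read_length - 1L
    data.frame(chrom = x$chrom[1], snp_pos = x$snp_pos[1],
               n_pairs = nrow(x), n_significant = sum(x$significant),
               cpg_disrupting = disr,
               nearby_other_asm = disr && any(other_sig))
  }))
  rownames(out) <- NULL
  out[order(out$chrom, out$snp_pos), , drop = FALSE]
}
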