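#' Annotate sites with CpG-island and gene-feature context and test enrichment
#'
#' Labels each site (and each background site) as island/non-island and with
#' one gene-feature category, then tests the target set against the
#' background: a two-sided Fisher's exact test per category on the 2x2
#' membership table, and, when a score table is supplied, a two-sided
#' Wilcoxon rank-sum test comparing score distributions (optionally
#' restricted to intergenic sites, where regulatory annotation cannot explain
#' conservation differences).
#'
#' Feature categories, by priority when intervals overlap: `promoter` (within
#' `promoter_width` bp upstream of a TSS, strand-aware), `first_exon`,
#' `first_intron`, `other_exon`, `other_intron`; outside genes, `intergenic`
#' when at least `intergenic_min` bp from the nearest gene (inclusive), else
#' `flanking`.
#'
#' @param sites data.frame with chrom, pos (target set).
#' @param background data.frame with chrom, pos (comparison universe).
#' @param islands data.frame with chrom, start, end (1-based closed), or NULL.
#' @param genes list with `genes` (gene, chrom, start, end, strand, tss) and
#'   `exons` (gene, exon, start, end), as in a `synthetic_reference`, or NULL.
#' @param scores data.frame with chrom, pos, score (conservation-like), or
#'   NULL to skip the rank-sum comparison.
#' @param promoter_width promoter extent upstream of the TSS (default 2000).
#' @param intergenic_min minimum distance from the nearest gene for the
#'   intergenic label (default 2000, inclusive: "at least 2 kb").
#' @param scores_intergenic_only restrict the score comparison to intergenic
#'   sites (default TRUE).
#' @return list with `sites` and `background` (annotated: island, feature),
#'   and `enrichment`: one row per test with target/background proportions,
#'   fold and p.
#' @export
annotate_and_enrich <- function(sites, background, islands = NULL,
                                genes = NULL, scores = NULL,
                                promoter_width = 2000L,
                                intergenic_min = 2000L,
                                scores_intergenic_only = TRUE) {
  if (is.null(background) || nrow(background) == 0) stopf("background set is empty")
  ann <- function(df) {
    df$island <- in_intervals(df, islands)
    df$feature <- feature_category(df, genes, promoter_width, intergenic_min)
    df
  }
  sites <- ann(sites)
  background <- ann(background)

  tests <- list()
  add_fisher <- function(name, t_in, b_in) {
    tab <- matrix(c(sum(t_in), sum(!t_in), sum(b_in), sum(!b_in)), 2)
    p <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1 else fisher.test(tab)$p.value
    pt <- mean(t_in); pb <- mean(b_in)
    tests[[length(tests) + 1L]] <<- data.frame(
      test = name, target_prop = pt, background_prop = pb,
      fold = if (pb > 0) pt / pb else NA_real_, p = p)
  }
  add_fisher("cpg_island", sites$island, background$island)
  for (feat in c("promoter", "first_exon", "first_intron", "other_exon",
                 "other_intron", "flanking", "intergenic")) {
    add_fisher(feat, sites$feature == feat, background$feature == feat)
  }
  if (!is.null(scores)) {
    skey <- pos_key(scores$chrom, scores$pos)
    pick <- function(df) {
      sel <- if (scores_intergenic_only) df$feature == "intergenic" else rep(TRUE, nrow(df))
      scores$score[match(pos_key(df$chrom, df$pos)[sel], skey)]
    }
    st <- pick(sites); sb <- pick(background)
    st <- st[!is.na(st)]; sb <- sb[!is.na(sb)]
    if (length(st) && length(sb)) {
      w <- wilcox.test(st, sb)
      tests[[length(tests) + 1L]] <- data.frame(
        test = "conservation_wilcoxon", target_prop = stats::median(st),
        background_prop = stats::median(sb), fold = NA_real_, p = w$p.value)
    }
  }
  list(sites = sites, background = background,
       enrichment = do.call(rbind, tests))
}

in_intervals <- function(df, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, nrow(df)))
  q <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, df$pos))
  s <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start, intervals$end))
  IRanges::overlapsAny(q, s)
}

feature_category <- function(df, genes, promoter_width, intergenic_min) {
  n <- nrow(df)
  if (is.null(genes) || is.null(genes$genes) || nrow(genes$genes) == 0) {
    return(rep("intergenic", n))
  }
  gt <- genes$genes
  ex <- genes$exons
  out <- rep(NA_character_, n)

  promoters <- data.frame(
    chrom = gt$chrom,
    start = ifelse(gt$strand == "+", pmax(gt$tss - promoter_width, 1), gt$tss + 1L),
    end = ifelse(gt$strand == "+", gt$tss - 1L, gt$tss + promoter_width)
  )
  first_ex <- merge(ex[ex$exon == 1, ], gt[, c("gene", "chrom")], by = "gene")
  other_ex <- merge(ex[ex$exon != 1, ], gt[, c("gene", "chrom")], by = "gene")
  introns <- derive_introns(gt, ex)

  assign_cat <- function(cat, ivs) {
    if (is.null(ivs) || nrow(ivs) == 0) return()
    hit <- in_intervals(df, ivs)
    out[is.na(out) & hit] <<- cat
  }
  assign_cat("promoter", promoters)
  assign_cat("first_exon", first_ex)
  assign_cat("first_intron", introns[introns$first, , drop = FALSE])
  assign_cat("other_exon", other_ex)
  assign_cat("other_intron", introns[!introns$first, , drop = FALSE])

  left <- which(is.na(out))
  if (length(left)) {
    q <- GenomicRanges::GRanges(df$chrom[left],
                                IRanges::IRanges(df$pos[left], df$pos[left]))
    s <- GenomicRanges::GRanges(gt$chrom, IRanges::IRanges(gt$start, gt$end))
    d <- GenomicRanges::distanceToNearest(q, s)
    dist <- rep(Inf, length(left))
    # GRanges distance is the gap size; +1 gives base-pair distance to the
    # nearest gene boundary (a site right next to a gene is 1 bp away)
    dist[S4Vectors_queryHits(d)] <- S4Vectors_mcols_distance(d) + 1
    out[left] <- ifelse(dist >= intergenic_min, "intergenic", "flanking")
  }
  out
}

# thin wrappers so the S4Vectors accessors stay in one place
S4Vectors_queryHits <- function(h) as.data.frame(h)$queryHits
S4Vectors_mcols_distance <- function(h) as.data.frame(h)$distance

derive_introns <- function(gt, ex) {
  rows <- list()
  for (g in unique(ex$gene)) {
    e <- ex[ex$gene == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    strand <- gt$strand[match(g, gt$gene)]
    chrom <- gt$chrom[match(g, gt$gene)]
    istart <- e$end[-nrow(e)] + 1L
    iend <- e$start[-1] - 1L
    ok <- istart <= iend
    if (!any(ok)) next
    # transcription order: the first intron abuts exon 1
    idx <- seq_len(sum(ok))
    first <- if (strand == "+") idx == 1 else idx == sum(ok)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = istart[ok], end = iend[ok], first = first)
  }
  do.call(rbind, rows) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               first = logical(0))
}
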