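test_that("a SNP and CpG never sharing a read produce no pair", {
  ref <- toy_reference()
  cpg <- ref$cpg$pos[10]
  snp_pos <- cpg - 100L  # far beyond one read length
  snps <- data.frame(chrom = "chrT", pos = snp_pos, ref = "A", var = "G",
                     ref_n = 10L, var_n = 10L, depth = 20L,
                     class = "callable", het = TRUE, genotype = 0.5,
                     cpg_disrupting = FALSE)
  cpgs <- data.frame(chrom = "chrT", pos = cpg, methylated = 10L,
                     total = 20L, pct = 50)
  aln <- toy_alignments("chrT", c(snp_pos - 5L, cpg - 5L), c("+", "+"),
                        rep(strrep("A", 36), 2))
  expect_equal(nrow(build_snp_cpg_tables(aln, snps, cpgs)), 0)
})

test_that("pair table margins match an independent per-read recount", {
  fx <- small_fixture()
  x <- fx$ind$C
  tabs <- x$tabs[!x$tabs$cpg_disrupting, , drop = FALSE]
  tabs <- head(tabs, 8)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    # naive recount: loop over alignments, classify each read independently
    rm <- ru <- vm <- vu <- 0L
    for (j in seq_len(nrow(x$aln))) {
      a <- x$aln[j, ]
      if (a$chrom != t$chrom) next
      meth_pos <- if (a$strand == "+") t$cpg_pos else t$cpg_pos + 1L
      if (a$start > min(t$snp_pos, meth_pos) || a$end < max(t$snp_pos, meth_pos)) next
      sb <- substring(a$fwd_seq, t$snp_pos - a$start + 1L, t$snp_pos - a$start + 1L)
      mb <- substring(a$fwd_seq, meth_pos - a$start + 1L, meth_pos - a$start + 1L)
      allele <- if (a$strand == "+") {
        if (t$ref == "C" && sb %in% c("C", "T")) "ref"
        else if (sb == t$ref) "ref"
        else if (t$var == "C" && sb %in% c("C", "T") && t$ref != "T") "var"
        else if (sb == t$var) "var" else NA
      } else {
        if (t$ref == "G" && sb %in% c("G", "A")) "ref"
        else if (sb == t$ref) "ref"
        else if (t$var == "G" && sb %in% c("G", "A") && t$ref != "A") "var"
        else if (sb == t$var) "var" else NA
      }
      meth <- if (a$strand == "+") {
        if (mb == "C") TRUE else if (mb == "T") FALSE else NA
      } else {
        if (mb == "G") TRUE else if (mb == "A") FALSE else NA
      }
      if (is.na(allele) || is.na(meth)) next
      if (allele == "ref" && meth) rm <- rm + 1L
      if (allele == "ref" && !meth) ru <- ru + 1L
      if (allele == "var" && meth) vm <- vm + 1L
      if (allele == "var" && !meth) vu <- vu + 1L
    }
    expect_equal(c(t$ref_meth, t$ref_unmeth, t$var_meth, t$var_unmeth),
                 c(rm, ru, vm, vu))
  }
})

test_that("CpG-disrupting pairs place every variant read in the unmethylated cell", {
  fx <- small_fixture()
  for (id in c("C", "D")) {
    dis <- fx$ind[[id]]$tabs[fx$ind[[id]]$tabs$cpg_disrupting, , drop = FALSE]
    if (nrow(dis)) expect_true(all(dis$var_meth == 0))
  }
})

test_that("a null table is never significant and degenerate margins are untestable", {
  pairs <- data.frame(chrom = "chr1", snp_pos = 10L, ref = "A", var = "G",
                      cpg_pos = 15L,
                      ref_meth = c(10L, 0L), ref_unmeth = c(10L, 20L),
                      var_meth = c(10L, 0L), var_unmeth = c(10L, 20L),
                      cpg_disrupting = FALSE)
  es <- test_asm(pairs)
  expect_equal(es$pairs$p[1], 1)
  expect_false(es$pairs$significant[1])
  expect_false(es$pairs$testable[2])  # empty methylated margin
  expect_equal(es$pairs$p[2], 1)
})

test_that("Fisher p equals the fixed-margin enumeration oracle", {
  expect_equal(fisher.test(matrix(c(15, 0, 0, 15), 2))$p.value,
               oracle_fisher_p(15, 0, 0, 15), tolerance = 1e-12)
  set.seed(99)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 6), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher.test(tab)$p.value,
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-9)
  }
})

test_that("a strongly imbalanced pair reports the correct delta and direction", {
  # one allele ~3% methylated, the other ~89%, at adequate depth
  pairs <- data.frame(chrom = "chr17", snp_pos = 100L, ref = "A", var = "G",
                      cpg_pos = 110L, ref_meth = 1L, ref_unmeth = 32L,
                      var_meth = 62L, var_unmeth = 8L, cpg_disrupting = FALSE)
  es <- test_asm(pairs)
  expect_equal(es$pairs$delta, 100 * (1 / 33 - 62 / 70), tolerance = 1e-9)
  expect_lt(es$pairs$delta, -85)
  expect_equal(es$pairs$more_methylated, "var")
  expect_lt(es$pairs$p, 1e-10)
})

test_that("Storey q-values are monotone in p and reduce to BH for small families", {
  p_small <- c(0.01, 0.2, 0.04, 0.9)
  expect_equal(storey_qvalue(p_small), p.adjust(p_small, "BH"))
  set.seed(7)
  p_big <- c(runif(900), rbeta(300, 0.2, 6))
  q <- storey_qvalue(p_big)
  o <- order(p_big)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q >= 0 & q <= 1))
  # pi0 < 1 under signal: Storey no less powerful than BH
  expect_true(all(q <= p.adjust(p_big, "BH") + 1e-12))
})

test_that("event-set comparison reproduces the cross-tissue style overlap arithmetic", {
  n_a <- 984; shared <- 834
  mk <- function(sig, dir) {
    pairs <- data.frame(chrom = "chr1", snp_pos = seq_len(n_a) * 100L,
                        ref = "A", var = "G", cpg_pos = seq_len(n_a) * 100L + 5L,
                        ref_meth = 20L, ref_unmeth = 2L, var_meth = 2L,
                        var_unmeth = 20L, cpg_disrupting = FALSE,
                        ref_total = 22L, var_total = 22L,
                        pct_ref = 90, pct_var = 10, delta = 80,
                        testable = TRUE, p = 1e-6, q = 1e-5,
                        significant = sig, more_methylated = dir)
    structure(list(pairs = pairs, fdr = 0.05), class = "asm_event_set")
  }
  a <- mk(rep(TRUE, n_a), rep("ref", n_a))
  b <- mk(c(rep(TRUE, shared), rep(FALSE, n_a - shared)), rep("ref", n_a))
  cmp <- compare_event_sets(a, b)
  expect_equal(cmp$overlap, shared / n_a)
  expect_equal(round(100 * cmp$overlap, 1), 84.8)
  expect_equal(cmp$direction_consistency, 1)
  expect_equal(cmp$allele_switch, 0)
  # identity comparison
  cmp_id <- compare_event_sets(a, a)
  expect_equal(cmp_id$overlap, 1)
  expect_equal(cmp_id$allele_switch, 0)
  # a flipped direction in b shows up as allele switching
  b_flip <- mk(rep(TRUE, n_a), rep("var", n_a))
  expect_equal(compare_event_sets(a, b_flip)$allele_switch, 1)
})

test_that("two relatives with the same planted genotype effects agree in direction", {
  fx <- small_fixture()
  tr <- fx$hs$truth
  geno_keys <- paste(tr$chrom, tr$snp_pos, tr$cpg_pos)[tr$class == "genotype"]
  a <- fx$ind$C$asm; b <- fx$ind$D$asm
  pa <- a$pairs; pb <- b$pairs
  ka <- paste(pa$chrom, pa$snp_pos, pa$cpg_pos)
  kb <- paste(pb$chrom, pb$snp_pos, pb$cpg_pos)
  shared <- intersect(ka[pa$significant & ka %in% geno_keys],
                      kb[pb$significant & kb %in% geno_keys])
  expect_gt(length(shared), 0)
  expect_true(all(pa$more_methylated[match(shared, ka)] ==
                    pb$more_methylated[match(shared, kb)]))
})

test_that("planted genotype effects at adequate per-allele depth are detected", {
  fx <- small_fixture()
  tr <- fx$hs$truth
  geno_keys <- paste(tr$chrom, tr$snp_pos, tr$cpg_pos)[tr$class == "genotype"]
  hit <- 0; tot <- 0
  for (id in c("C", "D")) {
    p <- fx$ind[[id]]$asm$pairs
    k <- paste(p$chrom, p$snp_pos, p$cpg_pos)
    sel <- k %in% geno_keys & p$ref_total >= 15 & p$var_total >= 15
    hit <- hit + sum(p$significant[sel]); tot <- tot + sum(sel)
  }
  expect_gt(tot, 5)
  expect_gte(hit / tot, 0.9)
})

test_that("per-SNP aggregation counts pairs and flags disrupting neighbourhoods", {
  fx <- small_fixture()
  es <- fx$ind$C$asm
  agg <- aggregate_asm_events(es)
  expect_equal(sum(agg$n_pairs), nrow(es$pairs))
  expect_equal(sum(agg$n_significant), sum(es$pairs$significant))
  k <- paste(es$pairs$chrom, es$pairs$snp_pos)
  expect_setequal(paste(agg$chrom, agg$snp_pos), unique(k))
})
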