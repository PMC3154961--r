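# Build a pile of identical-position toy reads over the toy reference with a
# chosen base at one position, forward strand unless stated.
pile_reads <- function(ref, start, n, edits = list(), strand = "+") {
  win <- substring(ref$chromosomes[["chrT"]], start, start + 35L)
  seqs <- rep(chartr("C", "T", win), n)  # fully converted background
  for (e in edits) {
    idx <- e$reads
    off <- e$pos - start + 1L
    for (i in idx) substr(seqs[i], off, off) <- e$base
  }
  toy_alignments("chrT", rep(start, n), rep(strand, n), seqs)
}

test_that("unanimous methylation at 14x is emitted and 13x is suppressed", {
  ref <- toy_reference()
  cpg <- ref$cpg$pos[3]
  start <- cpg - 10L
  aln14 <- pile_reads(ref, start, 14,
                      list(list(reads = 1:14, pos = cpg, base = "C")))
  out14 <- call_cpg_methylation(aln14, ref, min_depth = 14)
  got <- out14[out14$pos == cpg, ]
  expect_equal(got$pct, 100)
  expect_equal(got$total, 14)
  aln13 <- pile_reads(ref, start, 13,
                      list(list(reads = 1:13, pos = cpg, base = "C")))
  out13 <- call_cpg_methylation(aln13, ref, min_depth = 14)
  expect_false(cpg %in% out13$pos)
})

test_that("reverse-strand reads vote at the paired G and credit the C coordinate", {
  ref <- toy_reference()
  cpg <- ref$cpg$pos[4]
  start <- cpg - 8L
  win <- substring(ref$chromosomes[["chrT"]], start, start + 35L)
  # bottom strand: G (methylated) vs A (converted) at cpg + 1
  seqs <- rep(chartr("G", "A", win), 20)
  off <- cpg + 1L - start + 1L
  for (i in 1:8) substr(seqs[i], off, off) <- "G"
  aln <- toy_alignments("chrT", rep(start, 20), rep("-", 20), seqs)
  out <- call_cpg_methylation(aln, ref, min_depth = 14)
  got <- out[out$pos == cpg, ]
  expect_equal(got$methylated, 8)
  expect_equal(got$total, 20)
  expect_equal(got$pct, 40)
})

test_that("methylation calls are invariant to read order and strand partition", {
  fx <- small_fixture()
  aln <- fx$ind$C$aln
  shuffled <- aln[rev(seq_len(nrow(aln))), ]
  expect_equal(call_cpg_methylation(shuffled, fx$ref),
               call_cpg_methylation(aln, fx$ref))
})

test_that("observed methylation tracks planted propensity within exact binomial bounds", {
  fx <- small_fixture()
  cpg <- fx$ind$C$cpg
  null_keys <- setdiff(names(fx$hs$baseline$chr1),
                       as.character(fx$hs$overrides$cpg_pos))
  sel <- cpg[as.character(cpg$pos) %in% null_keys & cpg$total >= 20, ]
  sel <- head(sel[order(-sel$total), ], 25)
  p <- unname(fx$hs$baseline$chr1[as.character(sel$pos)])
  lo <- qbinom(0.005, sel$total, p)
  hi <- qbinom(0.995, sel$total, p)
  inside <- sel$methylated >= lo & sel$methylated <= hi
  # 99% interval per CpG; allow one excursion among 25
  expect_gte(sum(inside), length(inside) - 1)
})

test_that("SNP evidence thresholds are inclusive: 7 of 70 called, 7 of 71 not", {
  ref <- toy_reference()
  chars <- strsplit(ref$chromosomes[["chrT"]], "")[[1]]
  pos <- which(chars == "A" & seq_along(chars) > 100 & seq_along(chars) < 300)[1]
  start <- pos - 20L
  aln70 <- pile_reads(ref, start, 70,
                      list(list(reads = 1:7, pos = pos, base = "G")))
  out <- call_snps(aln70, ref)
  expect_equal(nrow(out), 1)
  expect_equal(out$var, "G")
  expect_equal(out$var_n, 7)
  expect_true(out$het)
  aln71 <- pile_reads(ref, start, 71,
                      list(list(reads = 1:7, pos = pos, base = "G")))
  expect_equal(nrow(call_snps(aln71, ref)), 0)
  aln60 <- pile_reads(ref, start, 60,
                      list(list(reads = 1:6, pos = pos, base = "G")))
  expect_equal(nrow(call_snps(aln60, ref)), 0)
})

test_that("forward-strand T over a reference C never yields a callable SNP", {
  ref <- toy_reference()
  cpg <- ref$cpg$pos[5]
  start <- cpg - 12L
  # half the reads carry T at the CpG C: pure conversion signal
  aln <- pile_reads(ref, start, 40,
                    list(list(reads = 1:20, pos = cpg, base = "C")))
  out <- call_snps(aln, ref)
  expect_false(any(out$class == "callable" & out$pos == cpg))
  # and an outright T pile at a non-CpG C is obscured, never callable
  cpos <- which(strsplit(ref$chromosomes[["chrT"]], "")[[1]] == "C")
  ncpg <- setdiff(cpos, c(ref$cpg$pos, ref$cpg$pos + 1L))
  p2 <- ncpg[ncpg > 150 & ncpg < 300][1]
  aln2 <- pile_reads(ref, p2 - 10L, 40, list())  # all converted to T anyway
  expect_false(any(call_snps(aln2, ref)$class == "callable"))
})

test_that("genotype codes follow the dosage convention with a 25-read floor", {
  expect_equal(genotype_code(0, 30, 30), 1)
  expect_equal(genotype_code(15, 12, 27), 0.5)
  expect_equal(genotype_code(24, 0, 24), NA_real_)
  expect_equal(genotype_code(12, 12, 24), NA_real_)
  expect_equal(genotype_code(28, 2, 30), 0)
  # boundary: exactly 25 reads, clean homozygote
  expect_equal(genotype_code(25, 0, 25), 0)
})

test_that("genotype calls recover truth exactly at depth-qualified planted SNPs", {
  fx <- small_fixture()
  sites <- fx$hs$snps[, c("chrom", "pos", "ref_base", "var_base")]
  names(sites) <- c("chrom", "pos", "ref", "var")
  g <- genotype_matrix(list(C = fx$ind$C$aln, D = fx$ind$D$aln), sites)
  checked <- 0
  for (id in c("C", "D")) {
    truth_code <- (fx$hs$haps[[id]]$h1$alleles + fx$hs$haps[[id]]$h2$alleles) / 2
    called <- g[, id]
    ok <- !is.na(called)
    expect_true(all(called[ok] == truth_code[ok]))
    checked <- checked + sum(ok)
  }
  expect_gt(checked, 20)
})

test_that("emitted SNP calls satisfy their own thresholds (self-audit)", {
  fx <- small_fixture()
  for (id in c("C", "D")) {
    s <- fx$ind[[id]]$snp
    expect_true(all(s$var_n >= 7))
    expect_true(all(s$var_n / s$depth >= 0.10))
    expect_true(all(!s$het | s$ref_n >= 7))
    expect_true(all(is.na(s$genotype) | s$depth >= 25))
  }
})

test_that("called SNPs coincide with planted variants on clean data", {
  fx <- small_fixture()
  planted <- paste(fx$hs$snps$chrom, fx$hs$snps$pos)
  for (id in c("C", "D")) {
    s <- fx$ind[[id]]$snp
    s <- s[s$class == "callable", ]
    expect_true(all(paste(s$chrom, s$pos) %in% planted))
    m <- match(paste(s$chrom, s$pos), planted)
    expect_equal(s$var, fx$hs$snps$var_base[m])
    expect_equal(s$cpg_disrupting, fx$hs$snps$cpg_disrupting[m])
  }
})
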