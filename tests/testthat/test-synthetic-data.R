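test_that("reference generator handles the empty chromosome", {
  ref <- build_reference(c(chr1 = 0L), seed = 1)
  expect_equal(nrow(ref$cpg), 0)
  expect_equal(nrow(ref$msp), 0)
  expect_equal(nrow(msp_fragments(ref)), 0)
})

test_that("MspI registry matches a naive substring scan", {
  ref <- build_reference(c(chr1 = 100000L), seed = 9)
  expect_equal(nrow(ref$msp), oracle_ccgg_count(ref$chromosomes[["chr1"]]))
  # every registered site spells CCGG; every CpG entry spells CG
  s <- ref$chromosomes[["chr1"]]
  expect_true(all(substring(s, ref$msp$pos, ref$msp$pos + 3) == "CCGG"))
  idx <- sample(nrow(ref$cpg), 200)
  expect_true(all(substring(s, ref$cpg$pos[idx], ref$cpg$pos[idx] + 1) == "CG"))
})

test_that("a hand-checked toy sequence yields the two expected MspI sites", {
  ref <- build_reference(sequence = c(chrX = "TTCCGGAAACCGGTT"))
  expect_equal(ref$msp$pos, c(3L, 10L))
})

test_that("reference build is deterministic and parameter-checked", {
  a <- build_reference(c(chr1 = 20000L), seed = 5)
  b <- build_reference(c(chr1 = 20000L), seed = 5)
  expect_identical(a$chromosomes, b$chromosomes)
  expect_error(build_reference(c(chr1 = -5L), seed = 1), "sizes")
  expect_error(build_reference(c(chr1 = 100L), gc = 1.4, seed = 1), "densities")
})

test_that("pedigree validation rejects malformed structures", {
  expect_error(pedigree(id = c("a", "b"), sex = c("F", "M"),
                        mother = c(NA, "a"), father = c(NA, NA)),
               "both parents or none")
  expect_error(pedigree(id = c("a", "b"), sex = c("F", "M"),
                        mother = c(NA, "z"), father = c(NA, "a")),
               "not in pedigree")
  expect_error(pedigree(id = c("a", "b"), sex = c("F", "M"),
                        mother = c("b", "a"), father = c("b", "a")),
               "cycle")
})

test_that("default pedigree has six assayed family members in three generations plus two unrelated", {
  ped <- default_family_pedigree()
  assayed <- ped[ped$assayed, ]
  expect_equal(nrow(assayed), 8)
  sons <- ped[ped$id %in% c("E", "F"), ]
  expect_true(all(sons$mother == "D" & sons$father == "C"))
  expect_equal(ped$mother[ped$id == "C"], "B")
  expect_equal(ped$mother[ped$id == "D"], "A")
  expect_true(all(ped$founder[ped$id %in% c("G", "H")]))
})

test_that("zero requested SNPs leaves every individual homozygous reference", {
  fx <- small_fixture()
  hs0 <- build_pedigree_genotypes(fx$ref, fx$ped, n_snps = 0, seed = 1)
  expect_equal(nrow(hs0$snps), 0)
  for (id in fx$ped$id) {
    expect_identical(hs0$haps[[id]]$h1$alleles, integer(0))
  }
})

test_that("transmission is Mendelian for every SNP and child", {
  hs <- small_fixture()$hs
  ped <- small_fixture()$ped
  for (id in ped$id[!ped$founder]) {
    row <- ped[ped$id == id, ]
    mom <- hs$haps[[row$mother]]; dad <- hs$haps[[row$father]]
    kid <- hs$haps[[id]]
    # the maternal haplotype is byte-identical to one of the mother's
    expect_true(identical(kid$h1$alleles, mom$h1$alleles) ||
                  identical(kid$h1$alleles, mom$h2$alleles))
    expect_true(identical(kid$h2$alleles, dad$h1$alleles) ||
                  identical(kid$h2$alleles, dad$h2$alleles))
    expect_equal(kid$h1$origin, "maternal")
    expect_equal(kid$h2$origin, "paternal")
  }
})

test_that("no planted variant forms a bisulfite-unobservable C/T pair or disturbs digestion context", {
  hs <- small_fixture()$hs
  pairs <- paste(hs$snps$ref_base, hs$snps$var_base)
  expect_false(any(pairs %in% c("C T", "T C")))
  # substitution never creates a CpG or changes local CCGG content
  for (i in seq_len(nrow(hs$snps))) {
    s <- hs$ref$chromosomes[[hs$snps$chrom[i]]]
    expect_false(asmfam:::unsafe_substitution(s, hs$snps$pos[i],
                                              hs$snps$var_base[i]))
  }
})

test_that("null effect fractions give identical propensities on both haplotypes", {
  fx <- small_fixture()
  hs0 <- build_pedigree_genotypes(fx$ref, fx$ped, n_snps = 30,
                                  cpg_disrupting_fraction = 0, seed = 7)
  hs0 <- assign_methylation_effects(hs0, c(genotype = 0, imprinted = 0),
                                    seed = 8)
  for (id in c("A", "C", "E")) {
    p1 <- haplotype_propensities(hs0, id, "h1", "chr1")
    p2 <- haplotype_propensities(hs0, id, "h2", "chr1")
    expect_identical(p1, p2)
  }
})

test_that("planted genotype deltas are centred on the configured 59.8-point default", {
  fx <- small_fixture()
  hs <- build_pedigree_genotypes(fx$ref, fx$ped, n_snps = 400,
                                 cpg_disrupting_fraction = 0, seed = 21)
  hs <- assign_methylation_effects(hs, c(genotype = 1, imprinted = 0), seed = 22)
  d <- hs$truth$delta[hs$truth$class == "genotype" & !duplicated(hs$truth$snp_id)]
  expect_gt(length(d), 50)
  expect_lt(abs(mean(d) - 59.8), 3 * 12 / sqrt(length(d)) + 1)
  expect_true(all(d > 0 & d <= 100))
})

test_that("imprinted loci separate propensities by parental origin regardless of allele", {
  hs <- small_fixture()$hs
  imp <- hs$truth[hs$truth$class == "imprinted", , drop = FALSE]
  expect_gt(nrow(imp), 0)
  ped <- small_fixture()$ped
  for (r in seq_len(min(nrow(imp), 5))) {
    cp <- imp$cpg_pos[r]
    for (id in ped$id[!ped$founder]) {
      pm <- haplotype_propensities(hs, id, "h1", imp$chrom[r])[cp]  # maternal
      pp <- haplotype_propensities(hs, id, "h2", imp$chrom[r])[cp]  # paternal
      expect_equal(abs(pm - pp) * 100, imp$delta[r], tolerance = 1e-8)
      if (imp$silenced_origin[r] == "maternal") expect_gt(pm, pp) else expect_gt(pp, pm)
    }
  }
})

test_that("fully converted effect-free reads carry no cytosine signal at reference positions", {
  fx <- small_fixture()
  hs0 <- build_pedigree_genotypes(fx$ref, fx$ped, n_snps = 0, seed = 3)
  hs0 <- assign_methylation_effects(hs0, c(genotype = 0, imprinted = 0), seed = 3)
  for (cn in names(hs0$baseline)) hs0$baseline[[cn]][] <- 0
  sim <- simulate_rrbs_reads(hs0, "E", depth = 10, conversion = 1,
                             error_rate = 0, seed = 5)
  expect_gt(nrow(sim$reads), 0)
  fwd <- sim$truth$strand == "+"
  # forward reads: no C anywhere a reference C sits under the window
  s <- fx$ref$chromosomes[["chr1"]]
  for (i in head(which(fwd), 200)) {
    win <- substring(s, sim$truth$start[i], sim$truth$start[i] + 35)
    rc_pos <- which(strsplit(win, "")[[1]] == "C")
    expect_false(any(substring(sim$reads$seq[i], rc_pos, rc_pos) == "C"))
  }
})

test_that("a propensity-1 CpG retains its cytosine in every covering forward read", {
  fx <- small_fixture()
  hs1 <- build_pedigree_genotypes(fx$ref, fx$ped, n_snps = 0, seed = 3)
  hs1 <- assign_methylation_effects(hs1, c(genotype = 0, imprinted = 0), seed = 3)
  # pick a CpG that a fragment-end window actually covers
  win <- asmfam:::fragment_windows(fx$ref, 36L, c(40L, 120L))
  cpgs <- as.integer(names(hs1$baseline$chr1))
  covered <- cpgs[vapply(cpgs, function(p) {
    any(win$wstart <= p & win$wend >= p + 1L)
  }, logical(1))]
  target <- covered[5]
  hs1$baseline$chr1[] <- 0
  hs1$baseline$chr1[as.character(target)] <- 1
  sim <- simulate_rrbs_reads(hs1, "E", depth = 30, seed = 6)
  fwd <- which(sim$truth$strand == "+" & sim$truth$start <= target &
                 sim$truth$start + 35 >= target)
  if (length(fwd)) {
    off <- target - sim$truth$start[fwd] + 1
    expect_true(all(substring(sim$reads$seq[fwd], off, off) == "C"))
  }
  rev <- which(sim$truth$strand == "-" & sim$truth$start <= target &
                 sim$truth$start + 35 >= target + 1)
  if (length(rev)) {
    # reverse reads report the paired G; in read space that is a C at the
    # mirrored offset
    off <- (sim$truth$start[rev] + 35) - (target + 1) + 1
    expect_true(all(substring(sim$reads$seq[rev], off, off) == "C"))
  }
})

test_that("reads are fixed-length windows inside size-selected fragments and FASTQ round-trips", {
  fx <- small_fixture()
  sim <- fx$ind$C$sim
  expect_true(all(nchar(sim$reads$seq) == 36))
  fr <- msp_fragments(fx$ref, c(40, 120))
  in_frag <- mapply(function(s) any(fr$start <= s & fr$end >= s + 35),
                    sim$truth$start)
  expect_true(all(in_frag))
  path <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, path)
  back <- read_fastq(path)
  expect_equal(back$seq, sim$reads$seq)
  expect_equal(back$id, sim$reads$id)
  # determinism: identical seed, byte-identical FASTQ
  sim2 <- simulate_rrbs_reads(fx$hs, "C", depth = 50, seed = 101)
  path2 <- tempfile(fileext = ".fastq")
  write_fastq(sim2$reads, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("simulator validates its parameter ranges", {
  hs <- small_fixture()$hs
  expect_error(simulate_rrbs_reads(hs, "C", conversion = 1.2, seed = 1), "conversion")
  expect_error(simulate_rrbs_reads(hs, "C", depth = 0, seed = 1), "depth")
  expect_error(simulate_rrbs_reads(hs, "C", fragment_range = c(120, 40), seed = 1),
               "inverted")
  expect_error(assign_methylation_effects(small_fixture()$hs,
                                          c(genotype = 0.8, imprinted = 0.5),
                                          seed = 1),
               "sum")
})
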