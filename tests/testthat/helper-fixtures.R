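# Shared simulation fixture, built once per test run. A 60 kb genome with the
# default family pedigree, 60 planted SNPs (25% CpG-disrupting), genotype and
# imprinted effects at the default magnitude, and clean (error-free, fully
# converted) reads at 50x for two individuals.
.fixture_env <- new.env()

small_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  ref <- build_reference(c(chr1 = 60000L), seed = 42)
  ped <- default_family_pedigree()
  hs <- build_pedigree_genotypes(ref, ped, n_snps = 60,
                                 cpg_disrupting_fraction = 0.25, seed = 43)
  hs <- assign_methylation_effects(hs, c(genotype = 0.35, imprinted = 0.10),
                                   seed = 44)
  mask <- reference_mappability(ref)
  per_ind <- list()
  for (id in c("C", "D")) {
    sim <- simulate_rrbs_reads(hs, id, depth = 50, seed = 100 + match(id, c("C", "D")))
    aln <- convert_and_align(sim$reads, ref, mappability_mask = mask)
    cpg <- call_cpg_methylation(aln, ref)
    snp <- call_snps(aln, ref)
    tabs <- build_snp_cpg_tables(aln, snp, cpg)
    per_ind[[id]] <- list(sim = sim, aln = aln, cpg = cpg, snp = snp,
                          tabs = tabs, asm = test_asm(tabs, sample_id = id))
  }
  .fixture_env$fx <- list(ref = ref, ped = ped, hs = hs, mask = mask,
                          ind = per_ind)
  .fixture_env$fx
}

# Hand-built alignment table on a supplied reference: `starts`/`strands`
# place each read, `seqs` are forward-orientation bases.
toy_alignments <- function(chrom, starts, strands, seqs, read_length = 36L) {
  data.frame(read_id = sprintf("t%04d", seq_along(starts)), chrom = chrom,
             start = starts, end = starts + read_length - 1L,
             strand = strands, score = 0L, fwd_seq = seqs,
             n_mismatch = 0L, mismatches = "")
}

# A deterministic toy reference: random sequence (unique 36-mers with high
# probability) with CpGs planted every 20 bp; no islands or genes.
toy_reference <- function(len = 400L, cpg_every = 20L) {
  asmfam:::with_seed(4242, {
    base <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    at <- seq(10L, len - 2L, by = cpg_every)
    base[at] <- "C"; base[at + 1L] <- "G"
    build_reference(sequence = c(chrT = paste(base, collapse = "")))
  })
}
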