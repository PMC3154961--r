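#' Plant SNPs and transmit haplotypes through a pedigree
#'
#' Places biallelic SNPs inside the sequencable end windows of size-selected
#' MspI fragments (the only territory 36-bp end reads can see), draws founder
#' alleles from per-SNP allele frequencies, and transmits whole-chromosome
#' haplotypes through the pedigree with recorded parental origins.
#'
#' Placement constraints keep the simulation analysable: no variant whose
#' allele pair is \{C, T\} is planted at an assayed position (bisulfite
#' conversion makes the pair indistinguishable on the forward strand, the
#' class the analysis must exclude); variants never create a new CpG or
#' create/destroy a CCGG site (digestion identical across haplotypes); a
#' configurable fraction of SNPs is CpG-disrupting, i.e. placed on the C or G
#' of an existing CpG with a variant that destroys the dinucleotide.
#'
#' @param ref a `synthetic_reference`.
#' @param ped a `pedigree`.
#' @param n_snps number of SNPs to place (at most one per fragment-end window).
#' @param cpg_disrupting_fraction fraction of SNPs that destroy a CpG.
#' @param af_range range of per-SNP variant allele frequencies for founders.
#' @param seed integer seed.
#' @param crossover_rate per-chromosome probability of a single uniform
#'   crossover during transmission; 0 (default) transmits whole chromosomes.
#' @param read_length read length defining the sequencable end windows.
#' @param fragment_range RRBS size-selection window in bp.
#' @return a `haplotype_set`: list with `ref`, `ped`, `snps` (snp_id, chrom,
#'   pos, ref_base, var_base, af, cpg_disrupting, disrupted_cpg), `pairs`
#'   (snp_id, chrom, cpg_pos: CpGs co-sequencable with the SNP), `haps`
#'   (per individual, two haplotypes with allele vectors and origin labels),
#'   and empty effect slots filled by [assign_methylation_effects()].
#' @export
build_pedigree_genotypes <- function(ref, ped, n_snps = 60,
                                     cpg_disrupting_fraction = 0.3,
                                     af_range = c(0.2, 0.5),
                                     seed = 1L,
                                     crossover_rate = 0,
                                     read_length = 36L,
                                     fragment_range = c(40L, 120L)) {
  validate_pedigree(ped)
  if (cpg_disrupting_fraction < 0 || cpg_disrupting_fraction > 1) {
    stopf("cpg_disrupting_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    placed <- place_snps(ref, n_snps, cpg_disrupting_fraction, read_length,
                         fragment_range)
    snps <- placed$snps
    n <- nrow(snps)
    snps$af <- if (n) runif(n, af_range[1], af_range[2]) else numeric(0)

    order_ids <- pedigree_order(ped)
    haps <- list()
    for (id in order_ids) {
      row <- ped[ped$id == id, ]
      if (row$founder) {
        haps[[id]] <- list(
          h1 = list(alleles = rbinom(n, 1, snps$af), origin = "maternal",
                    from = NA_character_, src = NA_character_),
          h2 = list(alleles = rbinom(n, 1, snps$af), origin = "paternal",
                    from = NA_character_, src = NA_character_)
        )
      } else {
        haps[[id]] <- list(
          h1 = transmit_haplotype(haps[[row$mother]], snps, "maternal",
                                  row$mother, crossover_rate),
          h2 = transmit_haplotype(haps[[row$father]], snps, "paternal",
                                  row$father, crossover_rate)
        )
      }
    }
    hs <- list(ref = ref, ped = ped, snps = snps, pairs = placed$pairs,
               haps = haps, baseline = NULL, overrides = NULL, truth = NULL,
               params = list(read_length = read_length,
                             fragment_range = fragment_range))
    class(hs) <- "haplotype_set"
    hs
  })
}

transmit_haplotype <- function(parent_haps, snps, origin, from, crossover_rate) {
  n <- nrow(snps)
  alleles <- integer(n)
  src <- character(0)
  for (cn in unique(snps$chrom)) {
    idx <- which(snps$chrom == cn)
    pick <- sample(c("h1", "h2"), 1)
    a <- parent_haps[[pick]]$alleles[idx]
    if (crossover_rate > 0 && runif(1) < crossover_rate && length(idx) > 1) {
      other <- setdiff(c("h1", "h2"), pick)
      bp <- sample(seq_along(idx), 1)
      a[bp:length(idx)] <- parent_haps[[other]]$alleles[idx][bp:length(idx)]
      pick <- paste(pick, other, sep = "x")
    }
    alleles[idx] <- a
    src <- c(src, pick)
  }
  if (n == 0) src <- NA_character_
  list(alleles = alleles, origin = origin, from = from,
       src = paste(unique(src), collapse = ","))
}

# Sequencable end windows of size-selected fragments. Forward reads cover the
# first `read_length` bases of a fragment, reverse reads the last.
fragment_windows <- function(ref, read_length, fragment_range) {
  fr <- msp_fragments(ref, fragment_range)
  if (!nrow(fr)) {
    return(data.frame(chrom = character(0), wstart = integer(0),
                      wend = integer(0), type = character(0)))
  }
  rbind(
    data.frame(chrom = fr$chrom, wstart = fr$start,
               wend = fr$start + read_length - 1L, type = "fwd"),
    data.frame(chrom = fr$chrom, wstart = fr$end - read_length + 1L,
               wend = fr$end, type = "rev")
  )
}

# CpGs measurable from a window: forward windows read the C directly; reverse
# windows read the paired G, so the G (C position + 1) must lie in the window.
window_cpgs <- function(cpg_pos, wstart, wend, type) {
  if (type == "fwd") {
    cpg_pos[cpg_pos >= wstart & cpg_pos <= wend]
  } else {
    cpg_pos[cpg_pos >= wstart & (cpg_pos + 1L) <= wend]
  }
}

# TRUE when the variant would be unidentifiable (or misidentified) on the
# strands that actually read this position. Bisulfite conversion reads an
# unmethylated C as T on the forward strand and a G as A on the reverse
# strand, so: a {C,T} allele pair is never identifiable; a variant C in
# forward-read territory converts and masquerades as a T variant; a variant G
# in reverse-read territory masquerades as A; and a G->A variant is masked as
# conversion signal on reverse reads, so it needs forward coverage.
unobservable_variant <- function(refb, var, in_fwd, in_rev) {
  if (setequal(c(refb, var), c("C", "T"))) return(TRUE)
  if (var == "C" && in_fwd) return(TRUE)
  if (var == "G" && in_rev) return(TRUE)
  if (refb == "G" && var == "A" && !in_fwd) return(TRUE)
  FALSE
}

# TRUE if substituting `var` at `pos` would create a new CpG or alter CCGG
# content anywhere nearby (which would change digestion between haplotypes).
unsafe_substitution <- function(seq, pos, var) {
  L <- nchar(seq)
  if (var == "G" && pos > 1 && substr(seq, pos - 1, pos - 1) == "C") return(TRUE)
  if (var == "C" && pos < L && substr(seq, pos + 1, pos + 1) == "G") return(TRUE)
  lo <- max(1, pos - 3)
  hi <- min(L, pos + 3)
  ctx <- substr(seq, lo, hi)
  new_ctx <- ctx
  substr(new_ctx, pos - lo + 1, pos - lo + 1) <- var
  length(motif_positions(new_ctx, "CCGG")) != length(motif_positions(ctx, "CCGG"))
}

place_snps <- function(ref, n_snps, cpg_disrupting_fraction, read_length,
                       fragment_range) {
  empty <- list(
    snps = data.frame(snp_id = character(0), chrom = character(0),
                      pos = integer(0), ref_base = character(0),
                      var_base = character(0), af = numeric(0),
                      cpg_disrupting = logical(0), disrupted_cpg = integer(0)),
    pairs = data.frame(snp_id = character(0), chrom = character(0),
                       cpg_pos = integer(0))
  )
  if (n_snps == 0) return(empty)
  win <- fragment_windows(ref, read_length, fragment_range)
  if (!nrow(win)) return(empty)

  msp_span <- unlist(lapply(seq_len(nrow(ref$msp)),
                            function(i) ref$msp$pos[i] + 0:3))
  msp_key <- pos_key(rep(ref$msp$chrom, each = 4), msp_span)

  # per-chromosome strand coverage of sequencable territory: which positions
  # are read by forward reads (fragment starts) and reverse reads (ends)
  cover <- list()
  for (cn in unique(win$chrom)) {
    L <- nchar(ref$chromosomes[[cn]])
    fwdcov <- logical(L); revcov <- logical(L)
    wc <- win[win$chrom == cn, , drop = FALSE]
    for (j in seq_len(nrow(wc))) {
      span <- wc$wstart[j]:wc$wend[j]
      if (wc$type[j] == "fwd") fwdcov[span] <- TRUE else revcov[span] <- TRUE
    }
    cover[[cn]] <- list(fwd = fwdcov, rev = revcov)
  }

  win <- win[sample.int(nrow(win)), , drop = FALSE]
  n_disrupt_target <- round(n_snps * cpg_disrupting_fraction)
  snp_rows <- list()
  pair_rows <- list()
  used_pos <- character(0)  # "chrom:pos" of planted SNPs (enforce spacing)
  n_disrupt <- 0

  for (w in seq_len(nrow(win))) {
    if (length(snp_rows) >= n_snps) break
    cn <- win$chrom[w]
    seq <- ref$chromosomes[[cn]]
    cpg_chr <- ref$cpg$pos[ref$cpg$chrom == cn]
    cpgs <- window_cpgs(cpg_chr, win$wstart[w], win$wend[w], win$type[w])
    if (!length(cpgs)) next
    want_disrupt <- n_disrupt < n_disrupt_target
    cand <- if (want_disrupt) {
      disrupting_candidate(seq, cpgs, win$wstart[w], win$wend[w], msp_key, cn,
                           cover[[cn]])
    } else {
      plain_candidate(seq, cpgs, win$wstart[w], win$wend[w], msp_key, cn,
                      cover[[cn]])
    }
    if (is.null(cand)) next
    near <- pos_key(cn, (cand$pos - 4):(cand$pos + 4))
    if (any(near %in% used_pos)) next
    used_pos <- c(used_pos, pos_key(cn, cand$pos))
    sid <- sprintf("snp%03d", length(snp_rows) + 1L)
    if (cand$disrupting) n_disrupt <- n_disrupt + 1
    snp_rows[[sid]] <- data.frame(
      snp_id = sid, chrom = cn, pos = cand$pos, ref_base = cand$ref,
      var_base = cand$var, cpg_disrupting = cand$disrupting,
      disrupted_cpg = cand$disrupted_cpg %||% NA_integer_
    )
    pair_rows[[sid]] <- data.frame(snp_id = sid, chrom = cn, cpg_pos = cpgs)
  }
  if (!length(snp_rows)) return(empty)
  snps <- do.call(rbind, snp_rows)
  rownames(snps) <- NULL
  snps$af <- numeric(nrow(snps))
  pairs <- do.call(rbind, pair_rows)
  rownames(pairs) <- NULL
  list(snps = snps[, names(empty$snps)], pairs = pairs)
}

# A CpG-destroying variant inside the window, mutating the C or the G of an
# existing CpG, subject to the observability and digestion-safety rules.
disrupting_candidate <- function(seq, cpgs, wstart, wend, msp_key, cn, cov) {
  for (cpg in shuffle(cpgs)) {
    for (side in shuffle(c("C", "G"))) {
      pos <- if (side == "C") cpg else cpg + 1L
      if (pos < wstart || pos > wend) next
      if (pos_key(cn, pos) %in% msp_key) next
      vars <- if (side == "C") c("A", "G") else c("T", "A", "C")
      for (v in shuffle(vars)) {
        if (unobservable_variant(side, v, cov$fwd[pos], cov$rev[pos])) next
        if (!unsafe_substitution(seq, pos, v)) {
          return(list(pos = pos, ref = side, var = v, disrupting = TRUE,
                      disrupted_cpg = cpg))
        }
      }
    }
  }
  NULL
}

plain_candidate <- function(seq, cpgs, wstart, wend, msp_key, cn, cov) {
  cpg_bases <- c(cpgs, cpgs + 1L)
  positions <- setdiff(wstart:wend, cpg_bases)
  for (pos in shuffle(positions)) {
    if (pos_key(cn, pos) %in% msp_key) next
    ref <- substr(seq, pos, pos)
    if (!ref %in% c("A", "C", "G", "T")) next
    for (v in shuffle(setdiff(c("A", "C", "G", "T"), ref))) {
      if (unobservable_variant(ref, v, cov$fwd[pos], cov$rev[pos])) next
      if (!unsafe_substitution(seq, pos, v)) {
        return(list(pos = pos, ref = ref, var = v, disrupting = FALSE,
                    disrupted_cpg = NULL))
      }
    }
  }
  NULL
}

#' Realise the DNA sequence of one haplotype
#'
#' @param hs a `haplotype_set`.
#' @param individual individual id.
#' @param hap `"h1"` (maternal) or `"h2"` (paternal).
#' @return named character vector of chromosome sequences with the carried
#'   variant alleles substituted.
#' @export
haplotype_sequence <- function(hs, individual, hap) {
  seqs <- hs$ref$chromosomes
  alleles <- hs$haps[[individual]][[hap]]$alleles
  carry <- which(alleles == 1L)
  for (i in carry) {
    cn <- hs$snps$chrom[i]
    substr(seqs[[cn]], hs$snps$pos[i], hs$snps$pos[i]) <- hs$snps$var_base[i]
  }
  seqs
}
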