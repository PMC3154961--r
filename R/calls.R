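# UTF-8 codes for the bases, used in the vectorised calling paths.
.A <- 65L; .C <- 67L; .G <- 71L; .T <- 84L

# Per-chromosome stack of alignment evidence: integer base matrix M
# (alignments x offsets, forward orientation), position matrix P, forward-
# strand flags, and a sorted cell index for fast per-position lookup.
aln_stack <- function(aln, read_length = 36L) {
  out <- list()
  for (cn in unique(aln$chrom)) {
    a <- aln[aln$chrom == cn, , drop = FALSE]
    n <- nrow(a)
    M <- int_matrix(a$fwd_seq, read_length)
    P <- outer(a$start, 0:(read_length - 1L), "+")
    ord <- order(as.vector(P))
    # double: findInterval would otherwise coerce on every lookup
    out[[cn]] <- list(n = n, fwd = a$strand == "+", M = M, P = P,
                      ord = ord, sortedP = as.double(as.vector(P)[ord]))
  }
  out
}

# Batch range lookup: one findInterval call for all positions (its input
# validation is O(n), so per-position calls would dominate).
cell_ranges <- function(st, positions) {
  k <- length(positions)
  fi <- findInterval(c(positions - 0.5, positions + 0.5), st$sortedP)
  list(lo = fi[seq_len(k)] + 1L, hi = fi[k + seq_len(k)])
}

# Cell indices (column-major into M/P) covering one genomic position, given
# its precomputed range.
cells_slice <- function(st, rng, i) {
  if (rng$hi[i] < rng$lo[i]) return(integer(0))
  st$ord[rng$lo[i]:rng$hi[i]]
}

#' Quantify per-CpG methylation from bisulfite alignments
#'
#' Forward-strand reads vote C (methylated) / T (unmethylated) at the C of
#' each reference CpG; reverse-strand reads vote G/A at the paired G and are
#' credited to the forward C coordinate, so each CpG is reported once. Other
#' bases at the position (sequencing errors, variant alleles) are ignored.
#' CpGs below `min_depth` combined votes are suppressed.
#'
#' @param aln alignments from [convert_and_align()].
#' @param ref a `synthetic_reference`.
#' @param min_depth minimum combined read depth to emit a call (default 14;
#'   use 10 for descriptive coverage tables).
#' @param read_length read length of the alignments.
#' @return data.frame: chrom, pos (1-based C position), methylated, total,
#'   pct.
#' @export
call_cpg_methylation <- function(aln, ref, min_depth = 14L, read_length = 36L) {
  stacks <- aln_stack(aln, read_length)
  rows <- list()
  for (cn in names(stacks)) {
    st <- stacks[[cn]]
    L <- nchar(ref$chromosomes[[cn]])
    is_cpg <- rep(FALSE, L + 1L)
    is_cpg[ref$cpg$pos[ref$cpg$chrom == cn]] <- TRUE
    fwdm <- matrix(st$fwd, st$n, read_length)
    Pv <- st$P
    sel_f <- fwdm & matrix(is_cpg[Pv], st$n)
    meth <- tabulate(Pv[sel_f & st$M == .C], nbins = L)
    unmeth <- tabulate(Pv[sel_f & st$M == .T], nbins = L)
    Pm1 <- Pv - 1L
    sel_r <- !fwdm & Pv > 1L & matrix(is_cpg[pmax(Pm1, 1L)], st$n)
    meth <- meth + tabulate(Pm1[sel_r & st$M == .G], nbins = L)
    unmeth <- unmeth + tabulate(Pm1[sel_r & st$M == .A], nbins = L)
    tot <- meth + unmeth
    keep <- which(tot >= min_depth)
    if (length(keep)) {
      rows[[cn]] <- data.frame(chrom = cn, pos = keep,
                               methylated = meth[keep], total = tot[keep])
    }
  }
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(0), pos = integer(0),
               methylated = integer(0), total = integer(0))
  out$pct <- if (nrow(out)) 100 * out$methylated / out$total else numeric(0)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Forward-orientation bases an allele can produce on each strand: bisulfite
# conversion makes an (unmethylated) C read as T on the forward strand and a
# G read as A on the reverse strand.
allele_obs_set <- function(allele, strand) {
  if (strand == "+" && allele == "C") return(c("C", "T"))
  if (strand == "-" && allele == "G") return(c("G", "A"))
  allele
}

# Assign observed bases to one of two alleles; NA where ambiguous under
# bisulfite conversion on that strand.
assign_allele <- function(base, strand, a1, a2) {
  out <- rep(NA_character_, length(base))
  for (s in c("+", "-")) {
    s1 <- allele_obs_set(a1, s)
    s2 <- allele_obs_set(a2, s)
    sel <- strand == s
    in1 <- sel & base %in% s1
    in2 <- sel & base %in% s2
    out[in1 & !in2] <- a1
    out[in2 & !in1] <- a2
  }
  out
}

# Allele-assigned counts for one position given the cell indices.
count_alleles_cells <- function(st, cells, refb, varb) {
  rowi <- ((cells - 1L) %% st$n) + 1L
  base <- intToUtf8(st$M[cells], multiple = TRUE)
  strand <- ifelse(st$fwd[rowi], "+", "-")
  al <- assign_allele(base, strand, refb, varb)
  c(ref_n = sum(al == refb, na.rm = TRUE),
    var_n = sum(al == varb, na.rm = TRUE),
    depth = length(cells))
}

# Allele-assigned read counts at given sites (chrom, pos, ref, var).
allele_counts_at <- function(stacks, sites) {
  n <- nrow(sites)
  ref_n <- var_n <- depth <- integer(n)
  for (cn in unique(sites$chrom)) {
    st <- stacks[[cn]]
    if (is.null(st)) next
    idx <- which(sites$chrom == cn)
    rng <- cell_ranges(st, sites$pos[idx])
    for (j in seq_along(idx)) {
      i <- idx[j]
      cells <- cells_slice(st, rng, j)
      if (!length(cells)) next
      cnt <- count_alleles_cells(st, cells, sites$ref[i], sites$var[i])
      ref_n[i] <- cnt["ref_n"]; var_n[i] <- cnt["var_n"]; depth[i] <- cnt["depth"]
    }
  }
  cbind(sites, data.frame(ref_n = ref_n, var_n = var_n, depth = depth))
}

#' Call SNPs from bisulfite alignments
#'
#' Tallies conversion-masked mismatches against the reference, assigns reads
#' to alleles with bisulfite-aware strand logic, and emits one call per
#' position passing the evidence thresholds: at least `min_variant_reads`
#' reads assigned to the variant allele, and the variant seen in at least
#' `min_variant_fraction` of all reads covering the position (both
#' inclusive). Candidates whose allele pair is \{C, T\} are emitted with
#' callability class `bisulfite_obscured` and never treated as callable (the
#' conversion signal cannot be separated from a genuine T allele). An
#' observed T is not counted as variant evidence where a C variant at the
#' same site explains it as an unmethylated cytosine (likewise A vs a G
#' variant on the reverse strand); where several candidate variants pass at
#' one position, the best-supported one is kept (multi-allelic sites are out
#' of scope).
#'
#' @param aln alignments from [convert_and_align()].
#' @param ref a `synthetic_reference`.
#' @param min_variant_reads minimum variant-assigned reads (default 7).
#' @param min_variant_fraction minimum variant fraction of all covering reads
#'   (default 0.10, inclusive).
#' @param min_ref_reads_het minimum reference-assigned reads to call the SNP
#'   heterozygous (default 7).
#' @param genotype_min_reads minimum total depth for a genotype code
#'   (default 25).
#' @param read_length read length of the alignments.
#' @return data.frame: chrom, pos, ref, var, ref_n, var_n, depth, class
#'   (callable | bisulfite_obscured), het, genotype (0/0.5/1/NA),
#'   cpg_disrupting.
#' @export
call_snps <- function(aln, ref, min_variant_reads = 7L,
                      min_variant_fraction = 0.10,
                      min_ref_reads_het = 7L,
                      genotype_min_reads = 25L,
                      read_length = 36L) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), var = character(0),
                      ref_n = integer(0), var_n = integer(0),
                      depth = integer(0), class = character(0),
                      het = logical(0), genotype = numeric(0),
                      cpg_disrupting = logical(0))
  if (!nrow(aln)) return(empty)
  stacks <- aln_stack(aln, read_length)
  rows <- list()
  for (cn in names(stacks)) {
    st <- stacks[[cn]]
    refint <- utf8ToInt(ref$chromosomes[[cn]])
    L <- length(refint)
    refM <- matrix(refint[st$P], st$n)
    fwdm <- matrix(st$fwd, st$n, read_length)
    mmcell <- st$M != refM &
      !(fwdm & refM == .C & st$M == .T) &
      !(!fwdm & refM == .G & st$M == .A)
    cand_pos <- sort(unique(as.vector(st$P)[as.vector(mmcell)]))
    if (!length(cand_pos)) next
    rng <- cell_ranges(st, cand_pos)
    for (ci in seq_along(cand_pos)) {
      pos <- cand_pos[ci]
      cells <- cells_slice(st, rng, ci)
      depth <- length(cells)
      rowi <- ((cells - 1L) %% st$n) + 1L
      base <- intToUtf8(st$M[cells], multiple = TRUE)
      strand <- ifelse(st$fwd[rowi], "+", "-")
      refb <- intToUtf8(refint[pos])
      is_mm <- base != refb & base %in% c("A", "C", "G", "T") &
        !(strand == "+" & refb == "C" & base == "T") &
        !(strand == "-" & refb == "G" & base == "A")
      vars <- unique(base[is_mm])
      if (!length(vars)) next
      # bisulfite parsimony: T evidence is subsumed by a C variant, A by G
      if ("C" %in% vars) vars <- setdiff(vars, "T")
      if ("G" %in% vars) vars <- setdiff(vars, "A")
      stats <- lapply(vars, function(v) {
        al <- assign_allele(base, strand, refb, v)
        list(var = v, ref_n = sum(al == refb, na.rm = TRUE),
             var_n = sum(al == v, na.rm = TRUE))
      })
      passing <- Filter(function(s) {
        s$var_n >= min_variant_reads && s$var_n / depth >= min_variant_fraction
      }, stats)
      if (!length(passing)) next
      bestv <- passing[[which.max(vapply(passing, `[[`, 0, "var_n"))]]
      cls <- if (setequal(c(refb, bestv$var), c("C", "T"))) "bisulfite_obscured" else "callable"
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cn, pos = pos, ref = refb, var = bestv$var,
        ref_n = bestv$ref_n, var_n = bestv$var_n, depth = depth, class = cls)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  out$het <- out$class == "callable" & out$ref_n >= min_ref_reads_het
  out$genotype <- genotype_code(out$ref_n, out$var_n, out$depth,
                                genotype_min_reads)
  nextb <- substring(ref$chromosomes[out$chrom], out$pos + 1L, out$pos + 1L)
  prevb <- substring(ref$chromosomes[out$chrom], pmax(out$pos - 1L, 1L),
                     pmax(out$pos - 1L, 1L))
  out$cpg_disrupting <- (out$ref == "C" & nextb == "G" & out$var != "C") |
    (out$ref == "G" & prevb == "C" & out$pos > 1L & out$var != "G")
  rownames(out) <- NULL
  out
}

#' Genotype codes from allele-assigned read counts
#'
#' Codes follow the dosage convention 0 = homozygous reference, 0.5 =
#' heterozygous, 1 = homozygous variant. A code requires at least `min_reads`
#' total covering reads; heterozygosity requires both alleles at >= 7 reads;
#' a homozygous call requires the minor allele below 7 reads, the major
#' allele at >= 90% of allele-assigned reads and at >= 7 reads. Anything
#' else is NA (no-call).
#'
#' @param ref_n,var_n allele-assigned read counts.
#' @param depth total covering reads.
#' @param min_reads minimum depth for any call (default 25).
#' @return numeric vector of 0, 0.5, 1 or NA.
#' @export
genotype_code <- function(ref_n, var_n, depth, min_reads = 25L) {
  n <- length(ref_n)
  out <- rep(NA_real_, n)
  informative <- ref_n + var_n
  frac_var <- ifelse(informative > 0, var_n / informative, NA_real_)
  ok <- depth >= min_reads & informative > 0
  out[ok & ref_n >= 7 & var_n >= 7] <- 0.5
  out[ok & var_n < 7 & !is.na(frac_var) & (1 - frac_var) >= 0.90 & ref_n >= 7] <- 0
  out[ok & ref_n < 7 & !is.na(frac_var) & frac_var >= 0.90 & var_n >= 7] <- 1
  out
}

#' Genotype matrix across individuals at a common set of SNP sites
#'
#' @param aln_list named list of alignment tables, one per individual.
#' @param sites data.frame with chrom, pos, ref, var.
#' @param min_reads minimum depth per genotype call.
#' @param read_length read length of the alignments.
#' @return numeric matrix (sites x individuals) of genotype codes with
#'   "chrom:pos" rownames.
#' @export
genotype_matrix <- function(aln_list, sites, min_reads = 25L,
                            read_length = 36L) {
  g <- matrix(NA_real_, nrow(sites), length(aln_list),
              dimnames = list(pos_key(sites$chrom, sites$pos),
                              names(aln_list)))
  for (id in names(aln_list)) {
    stacks <- aln_stack(aln_list[[id]], read_length)
    ac <- allele_counts_at(stacks, sites)
    g[, id] <- genotype_code(ac$ref_n, ac$var_n, ac$depth, min_reads)
  }
  g
}

#' Methylation percent matrix across individuals
#'
#' @param call_list named list of methylation call tables from
#'   [call_cpg_methylation()].
#' @return numeric matrix (CpGs x individuals) of percent methylation with
#'   "chrom:pos" rownames; NA where a sample lacks a call.
#' @export
methylation_matrix <- function(call_list) {
  keys <- sort(unique(unlist(lapply(call_list, function(x) pos_key(x$chrom, x$pos)))))
  m <- matrix(NA_real_, length(keys), length(call_list),
              dimnames = list(keys, names(call_list)))
  for (id in names(call_list)) {
    x <- call_list[[id]]
    m[pos_key(x$chrom, x$pos), id] <- x$pct
  }
  m
}
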