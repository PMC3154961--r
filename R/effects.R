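#' Assign per-haplotype CpG methylation propensities and planted effects
#'
#' Fills the `haplotype_set` with a locus-level baseline methylation propensity
#' for every reference CpG and plants three mutually exclusive effect classes
#' at the SNPs laid down by [build_pedigree_genotypes()]:
#'
#' * `genotype`: the two alleles carry different propensities at the CpGs
#'   co-sequencable with the SNP; the allele-to-propensity mapping is the same
#'   in every carrier (a cis-acting sequence effect).
#' * `imprinted`: propensity is tied to the parental origin of the haplotype
#'   (maternal vs paternal), independent of which allele it carries, so every
#'   individual is near 50% methylated at the locus.
#' * `cpg_disrupting`: decided at SNP placement; here the intact (reference)
#'   allele's propensity at the destroyed CpG is drawn high (0.7-1), since a
#'   variant that removes a CpG only produces an observable allelic methylation
#'   difference when the intact copy is methylated.
#'
#' Remaining SNPs are `null`: both haplotypes share the baseline everywhere.
#'
#' Baseline propensities are bimodal, as in somatic methylomes: CpGs inside
#' islands are drawn hypomethylated (Beta(1, 8)), CpGs outside islands from a
#' 75/25 mixture of Beta(8, 1) (methylated) and Beta(1, 8).
#'
#' @param hs a `haplotype_set` from [build_pedigree_genotypes()].
#' @param effect_fractions named numeric: fractions of the *non-disrupting*
#'   SNPs assigned the `genotype` and `imprinted` classes; must sum to <= 1.
#' @param mean_delta mean absolute allele difference in percentage points for
#'   planted effects; default 59.8.
#' @param delta_sd spread of the planted difference (percentage points); draws
#'   are rejected outside mean +/- 3 sd (and above 100), keeping the
#'   distribution symmetric about `mean_delta`.
#' @param seed integer seed.
#' @return the `haplotype_set` with `baseline`, `overrides` and `truth`
#'   filled. `truth` has one row per (SNP, affected CpG): snp_id, chrom,
#'   snp_pos, cpg_pos, class, delta (planted percentage-point difference),
#'   silenced_origin (for imprinted loci, the hypermethylated origin;
#'   methylation silences), p_a/p_b (propensity of ref/var allele, or
#'   maternal/paternal origin for imprinted loci).
#' @export
assign_methylation_effects <- function(hs,
                                       effect_fractions = c(genotype = 0.35,
                                                            imprinted = 0.10),
                                       mean_delta = 59.8,
                                       delta_sd = 12,
                                       seed = 1L) {
  fr_geno <- if ("genotype" %in% names(effect_fractions)) effect_fractions[["genotype"]] else 0
  fr_imp <- if ("imprinted" %in% names(effect_fractions)) effect_fractions[["imprinted"]] else 0
  if (fr_geno < 0 || fr_imp < 0 || fr_geno + fr_imp > 1) {
    stopf("effect fractions must be non-negative and sum to at most 1")
  }
  if (mean_delta <= 0 || mean_delta > 100) stopf("mean_delta must lie in (0, 100]")

  with_seed(seed, {
    hs$baseline <- draw_baseline(hs$ref)
    snps <- hs$snps
    truth_rows <- list()
    override_rows <- list()
    taken_cpgs <- character(0)

    # CpG-disrupting loci: force the intact allele methylated at the destroyed
    # CpG so the trivial mechanism is observable.
    for (i in which(snps$cpg_disrupting)) {
      cn <- snps$chrom[i]
      cpg <- snps$disrupted_cpg[i]
      p_hi <- runif(1, 0.7, 1)
      hs$baseline[[cn]][as.character(cpg)] <- p_hi
      taken_cpgs <- c(taken_cpgs, pos_key(cn, cpg))
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        snp_id = snps$snp_id[i], chrom = cn, snp_pos = snps$pos[i],
        cpg_pos = cpg, class = "cpg_disrupting", delta = 100 * p_hi,
        silenced_origin = "none", p_a = p_hi, p_b = 0)
    }

    plain <- which(!snps$cpg_disrupting)
    plain <- shuffle(plain)
    n_geno <- round(length(plain) * fr_geno)
    n_imp <- round(length(plain) * fr_imp)
    classes <- rep("null", length(plain))
    if (n_geno > 0) classes[seq_len(n_geno)] <- "genotype"
    if (n_imp > 0) classes[n_geno + seq_len(n_imp)] <- "imprinted"

    for (k in seq_along(plain)) {
      i <- plain[k]
      cls <- classes[k]
      sid <- snps$snp_id[i]
      cn <- snps$chrom[i]
      cpgs <- hs$pairs$cpg_pos[hs$pairs$snp_id == sid]
      cpgs <- cpgs[!(pos_key(cn, cpgs) %in% taken_cpgs)]
      if (cls == "null" || !length(cpgs)) {
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          snp_id = sid, chrom = cn, snp_pos = snps$pos[i],
          cpg_pos = NA_integer_, class = "null", delta = 0,
          silenced_origin = "none", p_a = NA_real_, p_b = NA_real_)
        next
      }
      taken_cpgs <- c(taken_cpgs, pos_key(cn, cpgs))
      delta <- draw_delta(mean_delta, delta_sd) / 100
      lo <- runif(1, 0, 1 - delta)
      hi <- lo + delta
      if (cls == "genotype") {
        ref_high <- runif(1) < 0.5
        p_ref <- if (ref_high) hi else lo
        p_var <- if (ref_high) lo else hi
        override_rows[[length(override_rows) + 1L]] <- data.frame(
          chrom = cn, cpg_pos = cpgs, scope = "allele", snp_id = sid,
          p_ref = p_ref, p_var = p_var, p_mat = NA_real_, p_pat = NA_real_)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          snp_id = sid, chrom = cn, snp_pos = snps$pos[i], cpg_pos = cpgs,
          class = "genotype", delta = delta * 100, silenced_origin = "none",
          p_a = p_ref, p_b = p_var)
      } else {
        mat_high <- runif(1) < 0.5
        p_mat <- if (mat_high) hi else lo
        p_pat <- if (mat_high) lo else hi
        override_rows[[length(override_rows) + 1L]] <- data.frame(
          chrom = cn, cpg_pos = cpgs, scope = "origin", snp_id = sid,
          p_ref = NA_real_, p_var = NA_real_, p_mat = p_mat, p_pat = p_pat)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          snp_id = sid, chrom = cn, snp_pos = snps$pos[i], cpg_pos = cpgs,
          class = "imprinted", delta = delta * 100,
          silenced_origin = if (mat_high) "maternal" else "paternal",
          p_a = p_mat, p_b = p_pat)
      }
    }
    hs$overrides <- do.call(rbind, override_rows) %||%
      data.frame(chrom = character(0), cpg_pos = integer(0),
                 scope = character(0), snp_id = character(0),
                 p_ref = numeric(0), p_var = numeric(0),
                 p_mat = numeric(0), p_pat = numeric(0))
    hs$truth <- do.call(rbind, truth_rows) %||%
      data.frame(snp_id = character(0), chrom = character(0),
                 snp_pos = integer(0), cpg_pos = integer(0),
                 class = character(0), delta = numeric(0),
                 silenced_origin = character(0), p_a = numeric(0),
                 p_b = numeric(0))
    rownames(hs$overrides) <- NULL
    rownames(hs$truth) <- NULL
    hs
  })
}

# Rejection draw: Normal(mean, sd) truncated symmetrically to
# [mean - 3 sd, mean + 3 sd] intersected with (0, 100].
draw_delta <- function(mean_delta, delta_sd) {
  lo <- max(mean_delta - 3 * delta_sd, 0.5)
  hi <- min(mean_delta + 3 * delta_sd, 100)
  repeat {
    d <- rnorm(1, mean_delta, delta_sd)
    if (d >= lo && d <= hi) return(d)
  }
}

draw_baseline <- function(ref) {
  out <- list()
  for (cn in names(ref$chromosomes)) {
    cpgs <- ref$cpg$pos[ref$cpg$chrom == cn]
    if (!length(cpgs)) {
      out[[cn]] <- setNames(numeric(0), character(0))
      next
    }
    isl <- ref$islands[ref$islands$chrom == cn, , drop = FALSE]
    in_isl <- rep(FALSE, length(cpgs))
    for (j in seq_len(nrow(isl))) {
      in_isl <- in_isl | (cpgs >= isl$start[j] & cpgs <= isl$end[j])
    }
    p <- numeric(length(cpgs))
    p[in_isl] <- rbeta(sum(in_isl), 1, 8)
    n_out <- sum(!in_isl)
    hi_arm <- runif(n_out) < 0.75
    p_out <- numeric(n_out)
    p_out[hi_arm] <- rbeta(sum(hi_arm), 8, 1)
    p_out[!hi_arm] <- rbeta(sum(!hi_arm), 1, 8)
    p[!in_isl] <- p_out
    out[[cn]] <- setNames(p, as.character(cpgs))
  }
  out
}

#' Methylation propensities of one haplotype
#'
#' Resolves baseline + planted overrides + CpG disruption into a per-position
#' propensity vector for a single haplotype of one individual.
#'
#' @param hs a `haplotype_set` with effects assigned.
#' @param individual individual id.
#' @param hap `"h1"` or `"h2"`.
#' @param chrom chromosome name.
#' @return numeric vector of chromosome length; NA everywhere except at the C
#'   positions of CpGs present on this haplotype, where it gives the
#'   probability that a sampled molecule is methylated there.
#' @export
haplotype_propensities <- function(hs, individual, hap, chrom) {
  if (is.null(hs$baseline)) stopf("effects not assigned; run assign_methylation_effects()")
  L <- nchar(hs$ref$chromosomes[[chrom]])
  prop <- rep(NA_real_, L)
  base <- hs$baseline[[chrom]]
  if (length(base)) prop[as.integer(names(base))] <- unname(base)

  alleles <- hs$haps[[individual]][[hap]]$alleles
  origin <- hs$haps[[individual]][[hap]]$origin
  ov <- hs$overrides[hs$overrides$chrom == chrom, , drop = FALSE]
  if (nrow(ov)) {
    snp_idx <- match(ov$snp_id, hs$snps$snp_id)
    carried <- alleles[snp_idx]
    allele_val <- ifelse(carried == 1L, ov$p_var, ov$p_ref)
    origin_val <- if (origin == "maternal") ov$p_mat else ov$p_pat
    prop[ov$cpg_pos] <- ifelse(ov$scope == "allele", allele_val, origin_val)
  }
  # CpG-disrupting variants carried on this haplotype remove the entry.
  disr <- which(hs$snps$cpg_disrupting & hs$snps$chrom == chrom & alleles == 1L)
  if (length(disr)) prop[hs$snps$disrupted_cpg[disr]] <- NA_real_
  prop
}
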