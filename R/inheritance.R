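#' Assign parental origin to heterozygous alleles through the pedigree
#'
#' For every heterozygous (code 0.5) genotype in a non-founder, trio rules
#' resolve which parent contributed the variant allele: a parent genotyped as
#' homozygous reference cannot have transmitted the variant (so it came from
#' the other parent, even when that parent is ungenotyped), and a parent
#' genotyped homozygous variant must have transmitted it. Both parents
#' heterozygous, or insufficient parental genotypes, leave the origin
#' ambiguous. A child variant that neither parent can supply is a Mendelian
#' inconsistency and is flagged and excluded. Founders' het sites are
#' labelled `founder`. Resolving an allele's origin in a parent through the
#' grandparents happens automatically because the parent has its own row in
#' the output (each generation is its own trio).
#'
#' @param geno genotype matrix (sites x individuals, "chrom:pos" rownames)
#'   from [genotype_matrix()], codes 0/0.5/1/NA.
#' @param ped a `pedigree`.
#' @return data.frame: individual, site (chrom:pos key), origin of the
#'   variant allele (maternal | paternal | ambiguous | founder),
#'   mendelian_error. One row per heterozygous genotype.
#' @export
assign_parental_origin <- function(geno, ped) {
  rows <- list()
  for (id in colnames(geno)) {
    prow <- ped[ped$id == id, ]
    if (nrow(prow) == 0) next
    het_sites <- rownames(geno)[!is.na(geno[, id]) & geno[, id] == 0.5]
    if (!length(het_sites)) next
    if (prow$founder) {
      rows[[id]] <- data.frame(individual = id, site = het_sites,
                               origin = "founder", mendelian_error = FALSE)
      next
    }
    mg <- if (prow$mother %in% colnames(geno)) geno[het_sites, prow$mother] else rep(NA_real_, length(het_sites))
    fg <- if (prow$father %in% colnames(geno)) geno[het_sites, prow$father] else rep(NA_real_, length(het_sites))
    origin <- rep("ambiguous", length(het_sites))
    err <- rep(FALSE, length(het_sites))
    # a parent without the variant forces the other parent as its source
    origin[!is.na(mg) & mg == 0] <- "paternal"
    origin[!is.na(fg) & fg == 0] <- "maternal"
    # a homozygous-variant parent must have transmitted it
    origin[!is.na(mg) & mg == 1] <- "maternal"
    origin[!is.na(fg) & fg == 1] <- "paternal"
    # inconsistencies: variant absent from both parents, or reference absent
    err <- (!is.na(mg) & !is.na(fg)) &
      ((mg == 0 & fg == 0) | (mg == 1 & fg == 1))
    origin[err] <- "ambiguous"
    rows[[id]] <- data.frame(individual = id, site = het_sites,
                             origin = origin, mendelian_error = err)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(individual = character(0), site = character(0),
               origin = character(0), mendelian_error = logical(0))
  rownames(out) <- NULL
  out
}

#' Classify ASM events as genotype-dependent or parental-origin
#'
#' Considers events significant in at least `min_members` individuals.
#' CpG-disrupting events are excluded outright (the association necessarily
#' follows the allele's sequence). For the rest, the informative members are
#' those where the event is significant and the variant allele's parental
#' origin is resolved; classification requires the variant origin to differ
#' between members (an origin switch), otherwise allele identity and origin
#' are confounded and the event is ambiguous. With a switch present:
#'
#' * the more-methylated *allele* (ref vs var) identical in every informative
#'   member: `genotype_dependent` (methylation follows the sequence);
#' * the more-methylated *haplotype origin* (maternal vs paternal) identical
#'   in every informative member while the allele identity switches:
#'   `parental_origin` (methylation follows the transmitting parent's sex);
#' * anything else: `ambiguous`.
#'
#' The rules are symmetric under swapping the reference/variant labels.
#'
#' @param event_sets named list of `asm_event_set`, one per individual.
#' @param origins origin assignments from [assign_parental_origin()].
#' @param min_members minimum members with a significant event (default 2).
#' @return data.frame: chrom, snp_pos, cpg_pos, mode (genotype_dependent |
#'   parental_origin | excluded_cpg_disrupting | ambiguous), informative
#'   (TRUE when an origin switch allowed classification), n_members,
#'   members (comma-joined ids of informative members).
#' @export
classify_inheritance_mode <- function(event_sets, origins, min_members = 2L) {
  per_member <- lapply(names(event_sets), function(id) {
    p <- event_sets[[id]]$pairs
    p <- p[p$significant, , drop = FALSE]
    if (!nrow(p)) return(NULL)
    data.frame(individual = id, chrom = p$chrom, snp_pos = p$snp_pos,
               cpg_pos = p$cpg_pos, cpg_disrupting = p$cpg_disrupting,
               more_methylated = p$more_methylated)
  })
  ev <- do.call(rbind, per_member)
  if (is.null(ev) || !nrow(ev)) {
    return(data.frame(chrom = character(0), snp_pos = integer(0),
                      cpg_pos = integer(0), mode = character(0),
                      informative = logical(0), n_members = integer(0),
                      members = character(0)))
  }
  ev$key <- pair_key(ev$chrom, ev$snp_pos, ev$cpg_pos)
  ev$site <- pos_key(ev$chrom, ev$snp_pos)
  ok <- origins[!origins$mendelian_error &
                  origins$origin %in% c("maternal", "paternal"), , drop = FALSE]
  ev$origin <- ok$origin[match(paste(ev$individual, ev$site),
                               paste(ok$individual, ok$site))]

  out <- lapply(split(ev, ev$key), function(x) {
    if (nrow(x) < min_members) return(NULL)
    base <- data.frame(chrom = x$chrom[1], snp_pos = x$snp_pos[1],
                       cpg_pos = x$cpg_pos[1])
    if (any(x$cpg_disrupting)) {
      return(cbind(base, mode = "excluded_cpg_disrupting", informative = FALSE,
                   n_members = nrow(x), members = ""))
    }
    inf <- x[!is.na(x$origin) & !is.na(x$more_methylated), , drop = FALSE]
    switching <- nrow(inf) >= 2 && length(unique(inf$origin)) > 1
    if (!switching) {
      return(cbind(base, mode = "ambiguous", informative = FALSE,
                   n_members = nrow(x), members = ""))
    }
    members <- paste(inf$individual, collapse = ",")
    mode <- if (length(unique(inf$more_methylated)) == 1) {
      "genotype_dependent"
    } else {
      # origin of the more-methylated haplotype: the variant's origin when the
      # variant allele is more methylated, else the other parent
      meth_origin <- ifelse(inf$more_methylated == "var", inf$origin,
                            ifelse(inf$origin == "maternal", "paternal",
                                   "maternal"))
      if (length(unique(meth_origin)) == 1) "parental_origin" else "ambiguous"
    }
    cbind(base, mode = mode, informative = TRUE, n_members = nrow(x),
          members = members)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    return(data.frame(chrom = character(0), snp_pos = integer(0),
                      cpg_pos = integer(0), mode = character(0),
                      informative = logical(0), n_members = integer(0),
                      members = character(0)))
  }
  rownames(out) <- NULL
  out[order(out$chrom, out$snp_pos, out$cpg_pos), , drop = FALSE]
}
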