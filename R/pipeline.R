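#' Assemble a pipeline configuration
#'
#' Collects every stage threshold with defaults matching the analysis design:
#' CpG depth 14, SNP evidence 7 reads / 10% fraction, heterozygosity 7
#' reference reads, genotype depth 25, ASM FDR 5% with Storey q-values,
#' model sd filter 25 and FDR 5%, ASE cutoff 25 reads with BH adjustment,
#' TSS window 5 kb, intergenic distance 2 kb, top 237 CpGs for clustering,
#' 36-bp reads from 40-120 bp MspI fragments.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param ... overrides for any default listed in the function body.
#' @return list of class `run_config` with a content hash in `$hash`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_sizes = c(chr1 = 150000L),
    gc = 0.45, island_density = 0.15, gene_density = 0.3, msp_density = 0.004,
    n_snps = 60L, cpg_disrupting_fraction = 0.25, af_range = c(0.2, 0.5),
    crossover_rate = 0,
    effect_fractions = c(genotype = 0.35, imprinted = 0.10),
    mean_delta = 59.8, delta_sd = 12,
    depth = 50, read_length = 36L, fragment_range = c(40L, 120L),
    conversion = 1.0, error_rate = 0,
    max_mismatches = 2L, mappability_mask = TRUE,
    min_cpg_depth = 14L,
    min_variant_reads = 7L, min_variant_fraction = 0.10,
    min_ref_reads_het = 7L, genotype_min_reads = 25L,
    asm_fdr = 0.05, q_method = "storey", min_per_allele = 5L,
    min_members = 2L,
    sd_min = 25, model_fdr = 0.05, top_n = 237L,
    ase_min_reads = 25L, ase_fdr = 0.05, tss_window = 5000L,
    intergenic_min = 2000L
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown)) stopf("unknown config fields: %s", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  cfg$hash <- fnv1a(paste(names(cfg), vapply(cfg, function(x) paste(format(x), collapse = ","), ""),
                          sep = "=", collapse = ";"))
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(cfg, k) as.integer((as.numeric(cfg$seed) * 1009 + k) %% 2147483629)

#' Run the full simulate-to-enrichment pipeline
#'
#' Executes every stage in order on one simulated cohort: reference and
#' pedigree simulation, methylation-effect planting, per-individual RRBS read
#' simulation, bisulfite alignment, CpG methylation and SNP calling, ASM
#' testing, parental-origin assignment and inheritance classification,
#' genotype-methylation model fitting on family members with held-out
#' prediction for unrelated individuals, clustering, and ASM-ASE enrichment
#' on simulated allelic expression counts. Reruns with an identical
#' configuration are identical.
#'
#' @param cfg a `run_config`.
#' @param pedigree_obj optional custom `pedigree` (default
#'   [default_family_pedigree()]).
#' @param keep_reads retain read tables in the bundle (default FALSE).
#' @return a `pipeline_result` list; see elements `ref`, `hs`, `alignments`,
#'   `cpg_calls`, `snp_calls`, `asm`, `origins`, `inheritance`, `geno`,
#'   `meth`, `fits`, `predictions`, `clustering`, `ase`, `enrichment`,
#'   `summary`.
#' @export
run_pipeline <- function(cfg = run_config(), pedigree_obj = NULL,
                         keep_reads = FALSE) {
  ped <- pedigree_obj %||% default_family_pedigree()
  ref <- build_reference(cfg$chrom_sizes, cfg$gc, cfg$island_density,
                         cfg$gene_density, cfg$msp_density,
                         seed = stage_seed(cfg, 1))
  hs <- build_pedigree_genotypes(ref, ped, cfg$n_snps,
                                 cfg$cpg_disrupting_fraction, cfg$af_range,
                                 seed = stage_seed(cfg, 2),
                                 crossover_rate = cfg$crossover_rate,
                                 read_length = cfg$read_length,
                                 fragment_range = cfg$fragment_range)
  hs <- assign_methylation_effects(hs, cfg$effect_fractions, cfg$mean_delta,
                                   cfg$delta_sd, seed = stage_seed(cfg, 3))

  assayed <- ped$id[ped$assayed]
  mask <- if (isTRUE(cfg$mappability_mask)) {
    reference_mappability(ref, cfg$read_length, cfg$fragment_range,
                          cfg$max_mismatches)
  } else FALSE
  alignments <- list(); cpg_calls <- list(); snp_calls <- list()
  asm <- list(); reads_kept <- list()
  for (i in seq_along(assayed)) {
    id <- assayed[i]
    sim <- simulate_rrbs_reads(hs, id, cfg$depth, cfg$read_length,
                               cfg$fragment_range, cfg$conversion,
                               cfg$error_rate, seed = stage_seed(cfg, 10 + i))
    if (keep_reads) reads_kept[[id]] <- sim
    aln <- convert_and_align(sim$reads, ref, cfg$max_mismatches, mask,
                             cfg$read_length, cfg$fragment_range)
    alignments[[id]] <- aln
    cpg_calls[[id]] <- call_cpg_methylation(aln, ref, cfg$min_cpg_depth,
                                            cfg$read_length)
    snp_calls[[id]] <- call_snps(aln, ref, cfg$min_variant_reads,
                                 cfg$min_variant_fraction,
                                 cfg$min_ref_reads_het,
                                 cfg$genotype_min_reads, cfg$read_length)
    tabs <- build_snp_cpg_tables(aln, snp_calls[[id]], cpg_calls[[id]],
                                 cfg$read_length)
    asm[[id]] <- test_asm(tabs, cfg$asm_fdr, cfg$q_method, cfg$min_per_allele,
                          sample_id = id)
  }

  # union of callable SNP sites across individuals -> genotype matrix
  site_tab <- unique(do.call(rbind, lapply(snp_calls, function(x) {
    x <- x[x$class == "callable", c("chrom", "pos", "ref", "var")]
    x
  })))
  site_tab <- site_tab[order(site_tab$chrom, site_tab$pos), , drop = FALSE]
  geno <- genotype_matrix(alignments, site_tab, cfg$genotype_min_reads,
                          cfg$read_length)
  meth <- methylation_matrix(cpg_calls)

  origins <- assign_parental_origin(geno, ped)
  inheritance <- classify_inheritance_mode(asm, origins, cfg$min_members)

  has_child <- ped$id %in% c(ped$mother, ped$father)
  family <- ped$id[ped$assayed & (!ped$founder | has_child)]
  unrelated <- setdiff(assayed, family)
  fits <- fit_genotype_models(meth[, family, drop = FALSE],
                              geno[, family, drop = FALSE],
                              sd_min = cfg$sd_min, fdr = cfg$model_fdr,
                              q_method = cfg$q_method,
                              max_distance = cfg$read_length - 1L)
  predictions <- lapply(unrelated, function(id) {
    predict_methylation(fits, geno[, id], meth[, id])
  })
  names(predictions) <- unrelated
  clustering <- if (length(assayed) >= 2 && nrow(meth) >= 2) {
    tryCatch(cluster_individuals(meth, cfg$top_n), error = function(e) NULL)
  } else NULL

  ase_sim <- simulate_ase_counts(hs, cfg$tss_window,
                                 seed = stage_seed(cfg, 50))
  ase <- test_ase(ase_sim$counts, cfg$ase_min_reads, cfg$ase_fdr)
  sig_events <- do.call(rbind, lapply(asm, function(es) {
    p <- es$pairs[es$pairs$significant, c("chrom", "snp_pos"), drop = FALSE]
    p
  }))
  sig_events <- unique(sig_events %||% data.frame(chrom = character(0),
                                                  snp_pos = integer(0)))
  enrichment <- asm_ase_enrichment(ase, sig_events, ref$genes$genes,
                                   cfg$tss_window)

  summary <- list(
    n_reads = NA_integer_,
    n_aligned = vapply(alignments, nrow, 0L),
    n_cpg_calls = vapply(cpg_calls, nrow, 0L),
    n_snp_calls = vapply(snp_calls, nrow, 0L),
    n_asm_significant = vapply(asm, function(x) sum(x$pairs$significant), 0L),
    inheritance_modes = if (nrow(inheritance)) table(inheritance$mode) else table(character(0)),
    n_model_fits = nrow(fits),
    n_model_significant = sum(fits$significant),
    prediction_r2 = vapply(predictions, function(p) p$r2, numeric(1)),
    ase_enrichment_p = enrichment$p,
    config_hash = cfg$hash
  )
  out <- list(config = cfg, ped = ped, ref = ref, hs = hs,
              reads = if (keep_reads) reads_kept else NULL,
              alignments = alignments, cpg_calls = cpg_calls,
              snp_calls = snp_calls, asm = asm, origins = origins,
              inheritance = inheritance, geno = geno, meth = meth,
              fits = fits, predictions = predictions,
              clustering = clustering, ase = ase, ase_truth = ase_sim$truth,
              enrichment = enrichment, family = family,
              unrelated = unrelated, summary = summary)
  class(out) <- "pipeline_result"
  out
}

#' Write pipeline result tables to a directory
#'
#' Emits deterministic TSV tables (stable column order and number formatting)
#' stamped with the configuration hash and seed, so reruns with the same
#' configuration are byte-identical.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_result_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash=%s seed=%d", result$config$hash,
                   result$config$seed)
  paths <- character(0)
  emit <- function(df, name) {
    path <- file.path(dir, paste0(name, ".tsv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) formatC(x, digits = 10, format = "g"))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paths <<- c(paths, path)
  }
  asm_all <- do.call(rbind, lapply(names(result$asm), function(id) {
    cbind(individual = id, result$asm[[id]]$pairs)
  }))
  emit(asm_all, "asm_pairs")
  meth_all <- do.call(rbind, lapply(names(result$cpg_calls), function(id) {
    cbind(individual = id, result$cpg_calls[[id]])
  }))
  emit(meth_all, "methylation")
  snp_all <- do.call(rbind, lapply(names(result$snp_calls), function(id) {
    cbind(individual = id, result$snp_calls[[id]])
  }))
  emit(snp_all, "snps")
  # BED (0-based half-open) of CpGs significant in any individual
  sig_cpg <- unique(do.call(rbind, lapply(result$asm, function(es) {
    es$pairs[es$pairs$significant, c("chrom", "cpg_pos"), drop = FALSE]
  })))
  if (!is.null(sig_cpg) && nrow(sig_cpg)) {
    sig_cpg <- sig_cpg[order(sig_cpg$chrom, sig_cpg$cpg_pos), , drop = FALSE]
    bed <- file.path(dir, "asm_cpgs.bed")
    writeLines(sprintf("%s\t%d\t%d", sig_cpg$chrom, sig_cpg$cpg_pos - 1L,
                       sig_cpg$cpg_pos + 1L), bed)
    paths <- c(paths, bed)
  }
  emit(result$origins, "origins")
  emit(result$inheritance, "inheritance")
  emit(as.data.frame(result$fits), "model_fits")
  emit(result$ase, "ase")
  invisible(paths)
}
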