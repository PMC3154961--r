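#' Build a synthetic reference genome for RRBS simulation
#'
#' Generates one or more random chromosomes with controllable GC content,
#' CpG-island intervals (locally CpG-enriched), gene models with exon/intron
#' structure, and planted MspI (CCGG) recognition sites whose spacing yields a
#' substantial pool of size-selectable restriction fragments. After sequence
#' assembly the CpG registry and MspI site list are re-scanned from the final
#' sequence, so they are always consistent with the sequence content.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param gc baseline GC fraction outside islands, in \[0, 1\].
#' @param island_density target fraction of bases inside CpG islands, \[0, 1\].
#' @param gene_density target fraction of bases covered by gene models, \[0, 1\].
#' @param msp_density expected CCGG motif starts per base; spacing is drawn as
#'   a mixture of short (40-120 bp, sequencable) and long gaps.
#' @param seed integer seed; the build is deterministic for a fixed seed.
#' @param island_length two-element range of island lengths in bp.
#' @param sequence optional named character vector of chromosome sequences to
#'   use verbatim instead of simulating (registries are scanned from it;
#'   islands/genes empty unless supplied via `islands`/`genes`).
#' @param islands,genes optional annotation to attach when `sequence` is given:
#'   `islands` a data.frame (chrom, start, end), `genes` a list with elements
#'   `genes` and `exons` as produced by the simulator.
#' @return an object of class `synthetic_reference`: a list with elements
#'   `chromosomes` (named character), `cpg` (data.frame chrom, pos of the C of
#'   each forward-strand CpG, 1-based), `msp` (data.frame chrom, pos of each
#'   CCGG start), `islands` (chrom, start, end; 1-based closed intervals),
#'   `genes` (a list: `genes` data.frame with gene, chrom, start, end, strand,
#'   tss; `exons` data.frame with gene, exon, start, end).
#' @export
build_reference <- function(chrom_sizes = c(chr1 = 100000L),
                            gc = 0.45,
                            island_density = 0.15,
                            gene_density = 0.3,
                            msp_density = 0.004,
                            seed = 1L,
                            island_length = c(300L, 800L),
                            sequence = NULL,
                            islands = NULL,
                            genes = NULL) {
  if (is.null(sequence)) {
    if (any(chrom_sizes < 0)) stopf("chromosome sizes must be >= 0")
    for (d in c(gc, island_density, gene_density)) {
      if (is.na(d) || d < 0 || d > 1) stopf("densities must lie in [0, 1]")
    }
    if (msp_density < 0 || msp_density > 1) stopf("msp_density must lie in [0, 1]")
    if (is.null(names(chrom_sizes))) {
      names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
    }
    built <- with_seed(seed, {
      lapply(names(chrom_sizes), function(cn) {
        simulate_chromosome(chrom_sizes[[cn]], gc, island_density, gene_density,
                            msp_density, island_length)
      })
    })
    names(built) <- names(chrom_sizes)
    chromosomes <- vapply(built, `[[`, character(1), "seq")
    islands <- do.call(rbind, lapply(names(built), function(cn) {
      df <- built[[cn]]$islands
      if (nrow(df)) cbind(chrom = cn, df) else NULL
    }))
    gene_tab <- do.call(rbind, lapply(names(built), function(cn) {
      df <- built[[cn]]$genes
      if (!is.null(df) && nrow(df)) cbind(chrom = cn, df) else NULL
    }))
    exon_tab <- do.call(rbind, lapply(names(built), function(cn) built[[cn]]$exons))
    genes <- list(genes = gene_tab %||% empty_gene_table(),
                  exons = exon_tab %||% empty_exon_table())
  } else {
    if (is.null(names(sequence))) names(sequence) <- paste0("chr", seq_along(sequence))
    chromosomes <- toupper(sequence)
    genes <- genes %||% list(genes = empty_gene_table(), exons = empty_exon_table())
  }
  islands <- islands %||% data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0))
  ref <- list(
    chromosomes = chromosomes,
    cpg = scan_positions(chromosomes, "CG"),
    msp = scan_positions(chromosomes, "CCGG"),
    islands = as.data.frame(islands),
    genes = genes
  )
  class(ref) <- "synthetic_reference"
  attr(ref, "cache") <- new.env(parent = emptyenv())
  validate_reference(ref)
  ref
}

empty_gene_table <- function() {
  data.frame(chrom = character(0), gene = character(0), start = integer(0),
             end = integer(0), strand = character(0), tss = integer(0))
}

empty_exon_table <- function() {
  data.frame(gene = character(0), exon = integer(0), start = integer(0),
             end = integer(0))
}

scan_positions <- function(chromosomes, motif) {
  out <- lapply(names(chromosomes), function(cn) {
    p <- motif_positions(chromosomes[[cn]], motif)
    if (length(p)) data.frame(chrom = cn, pos = p) else NULL
  })
  out <- do.call(rbind, out)
  out %||% data.frame(chrom = character(0), pos = integer(0))
}

simulate_chromosome <- function(len, gc, island_density, gene_density,
                                msp_density, island_length) {
  if (len == 0) {
    return(list(seq = "", islands = data.frame(start = integer(0), end = integer(0)),
                genes = NULL, exons = NULL))
  }
  bases <- c("A", "C", "G", "T")
  p_bg <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seq <- sample(bases, len, replace = TRUE, prob = p_bg)

  # Island intervals: sample non-overlapping until the target mass is reached.
  islands <- data.frame(start = integer(0), end = integer(0))
  target <- island_density * len
  covered <- 0
  tries <- 0
  while (covered < target && tries < 10000 && len > island_length[2]) {
    w <- sample(island_length[1]:island_length[2], 1)
    s <- sample.int(len - w, 1)
    if (!any(s <= islands$end + 50 & (s + w - 1) >= islands$start - 50)) {
      islands <- rbind(islands, data.frame(start = s, end = s + w - 1))
      covered <- covered + w
    }
    tries <- tries + 1
  }
  islands <- islands[order(islands$start), , drop = FALSE]

  in_island <- rep(FALSE, len)
  for (i in seq_len(nrow(islands))) in_island[islands$start[i]:islands$end[i]] <- TRUE

  # CpG planting: dense inside islands, sparse outside.
  seq <- plant_cpgs(seq, which(in_island), rate = 0.06)
  seq <- plant_cpgs(seq, which(!in_island), rate = 0.008)

  # MspI sites: walk along the chromosome with a short/long spacing mixture so
  # that roughly half of the inter-site gaps fall in the 40-120 bp
  # size-selection window.
  mean_gap <- if (msp_density > 0) 1 / msp_density else Inf
  long_gap <- max(150, 2 * mean_gap - 80)
  pos <- sample(20:120, 1)
  while (pos + 4 <= len - 4) {
    seq[pos:(pos + 3)] <- c("C", "C", "G", "G")
    gap <- if (runif(1) < 0.5) sample(44:116, 1) else round(runif(1, 0.6 * long_gap, 1.4 * long_gap))
    pos <- pos + gap
  }

  gene_tab <- NULL
  exon_tab <- NULL
  if (gene_density > 0 && len > 4000) {
    g <- place_genes(len, gene_density)
    gene_tab <- g$genes
    exon_tab <- g$exons
  }
  list(seq = paste(seq, collapse = ""), islands = islands,
       genes = gene_tab, exons = exon_tab)
}

plant_cpgs <- function(seq, at, rate) {
  if (!length(at)) return(seq)
  n <- max(0, round(length(at) * rate))
  if (n == 0) return(seq)
  starts <- sort(sample(at[at < length(seq)], min(n, sum(at < length(seq)))))
  starts <- starts[c(TRUE, diff(starts) > 1)]
  seq[starts] <- "C"
  seq[starts + 1] <- "G"
  seq
}

place_genes <- function(len, gene_density) {
  genes <- data.frame(gene = character(0), start = integer(0), end = integer(0),
                      strand = character(0), tss = integer(0))
  exons <- empty_exon_table()
  covered <- 0
  k <- 0
  tries <- 0
  while (covered < gene_density * len && tries < 5000) {
    w <- sample(2000:5000, 1)
    s <- sample.int(len - w, 1)
    e <- s + w - 1
    if (!any(s <= genes$end + 500 & e >= genes$start - 500)) {
      k <- k + 1
      strand <- sample(c("+", "-"), 1)
      gid <- sprintf("gene%03d", k)
      tss <- if (strand == "+") s else e
      genes <- rbind(genes, data.frame(gene = gid, start = s, end = e,
                                       strand = strand, tss = tss))
      # Three exons laid out from the TSS end; intron boundaries in between.
      el <- round(w * c(0.08, 0.1, 0.12))
      gaps <- round(w * c(0.3, 0.3))
      if (strand == "+") {
        e1 <- c(s, s + el[1] - 1)
        e2 <- c(e1[2] + gaps[1], e1[2] + gaps[1] + el[2] - 1)
        e3 <- c(e2[2] + gaps[2], min(e, e2[2] + gaps[2] + el[3] - 1))
      } else {
        e1 <- c(e - el[1] + 1, e)
        e2 <- c(e1[1] - gaps[1] - el[2] + 1, e1[1] - gaps[1])
        e3 <- c(max(s, e2[1] - gaps[2] - el[3] + 1), e2[1] - gaps[2])
      }
      ex <- rbind(e1, e2, e3)
      exons <- rbind(exons, data.frame(gene = gid, exon = 1:3,
                                       start = pmin(ex[, 1], ex[, 2]),
                                       end = pmax(ex[, 1], ex[, 2])))
      covered <- covered + w
    }
    tries <- tries + 1
  }
  list(genes = genes, exons = exons)
}

validate_reference <- function(ref) {
  # Spot-check the registry against sequence content (it is scanned from the
  # final sequence, so this guards against coordinate bookkeeping slips only).
  n_check <- min(nrow(ref$cpg), 50L)
  if (n_check > 0) {
    idx <- seq_len(n_check)
    di <- substr(rep(ref$chromosomes[ref$cpg$chrom[idx]], 1),
                 ref$cpg$pos[idx], ref$cpg$pos[idx] + 1L)
    if (!all(di == "CG")) stopf("CpG registry inconsistent with sequence")
  }
  lens <- nchar(ref$chromosomes)
  if (nrow(ref$islands)) {
    ok <- ref$islands$start >= 1 & ref$islands$end <= lens[ref$islands$chrom]
    if (!all(ok)) stopf("island intervals outside chromosome bounds")
  }
  gt <- ref$genes$genes
  if (!is.null(gt) && nrow(gt)) {
    ok <- gt$start >= 1 & gt$end <= lens[gt$chrom]
    if (!all(ok)) stopf("gene intervals outside chromosome bounds")
  }
  invisible(ref)
}

#' MspI restriction fragments of a reference
#'
#' MspI cuts C^CGG; with a site whose first C is at position p, the cut falls
#' between p and p+1. Internal fragments run from one cut to the next; terminal
#' chromosome pieces lack an adapter-ligatable MspI end and are excluded.
#'
#' @param ref a `synthetic_reference`.
#' @param size_range two-element numeric; keep fragments whose length lies in
#'   this closed range (the RRBS size selection), default 40-120 bp.
#' @return data.frame with chrom, start, end (1-based closed) and length.
#' @export
msp_fragments <- function(ref, size_range = c(40L, 120L)) {
  if (size_range[1] > size_range[2]) stopf("fragment size range is inverted")
  out <- lapply(unique(ref$msp$chrom), function(cn) {
    p <- sort(ref$msp$pos[ref$msp$chrom == cn])
    if (length(p) < 2) return(NULL)
    start <- p[-length(p)] + 1L
    end <- p[-1]
    data.frame(chrom = cn, start = start, end = end, length = end - start + 1L)
  })
  out <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               length = integer(0))
  out[out$length >= size_range[1] & out$length <= size_range[2], , drop = FALSE]
}

#' Write a reference to FASTA
#' @param ref a `synthetic_reference`.
#' @param path output FASTA file.
#' @export
write_reference_fasta <- function(ref, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$chromosomes), path)
  invisible(path)
}
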