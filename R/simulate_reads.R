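#' Simulate RRBS bisulfite reads for one individual
#'
#' Digests each haplotype with MspI (C^CGG), size-selects fragments, samples
#' molecules per fragment, draws per-molecule CpG methylation states from the
#' haplotype's propensities, applies bisulfite conversion and sequencing
#' errors, and emits 36-bp single-end reads from fragment ends: molecules read
#' from the top strand yield forward reads covering the first `read_length`
#' bases of the fragment, molecules read from the bottom strand yield reverse
#' reads covering the last `read_length` bases (reported 5'->3' as sequenced).
#'
#' Conversion model: an unmethylated cytosine is read as T with probability
#' `conversion` (incomplete conversion leaves it as C, inflating apparent
#' methylation); a methylated CpG cytosine is always read as C. Methylation is
#' CpG-only and symmetric across strands, with states drawn independently per
#' molecule and per CpG from the haplotype propensity. On the bottom strand
#' the same logic appears in forward coordinates as G (methylated) vs A
#' (converted).
#'
#' @param hs a `haplotype_set` with effects assigned.
#' @param individual individual id (must be assayed in the pedigree).
#' @param depth expected total read depth at each fragment end (both
#'   haplotypes combined); per haplotype and end, molecule counts are
#'   Poisson(depth/2).
#' @param read_length read length in bp (default 36).
#' @param fragment_range size-selection window (default 40-120 bp); fragments
#'   shorter than `read_length` are dropped.
#' @param conversion bisulfite conversion efficiency in \[0, 1\].
#' @param error_rate per-base substitution error probability, applied last.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with `reads` (data.frame id, seq, qual) and `truth`
#'   (data.frame id, individual, chrom, start of the covered window in
#'   forward coordinates, strand, hap). Truth is never encoded in the reads.
#' @export
simulate_rrbs_reads <- function(hs, individual, depth = 50,
                                read_length = 36L,
                                fragment_range = c(40L, 120L),
                                conversion = 1.0, error_rate = 0,
                                seed = 1L) {
  if (conversion < 0 || conversion > 1) stopf("conversion must lie in [0, 1]")
  if (error_rate < 0 || error_rate > 1) stopf("error_rate must lie in [0, 1]")
  if (depth <= 0) stopf("depth must be > 0")
  if (fragment_range[1] > fragment_range[2]) stopf("fragment size range is inverted")
  if (!individual %in% hs$ped$id) stopf("unknown individual '%s'", individual)

  with_seed(seed, {
    out_seq <- character(0)
    truth <- list()
    for (hap in c("h1", "h2")) {
      hseqs <- haplotype_sequence(hs, individual, hap)
      for (cn in names(hseqs)) {
        hseq <- hseqs[[cn]]
        sites <- motif_positions(hseq, "CCGG")
        if (length(sites) < 2) next
        fstart <- sites[-length(sites)] + 1L
        fend <- sites[-1]
        flen <- fend - fstart + 1L
        keep <- flen >= max(fragment_range[1], read_length) & flen <= fragment_range[2]
        if (!any(keep)) next
        fstart <- fstart[keep]; fend <- fend[keep]
        prop <- haplotype_propensities(hs, individual, hap, cn)
        is_cpg_c <- rep(FALSE, nchar(hseq))
        is_cpg_c[motif_positions(hseq, "CG")] <- TRUE

        for (side in c("top", "bottom")) {
          nmol <- rpois(length(fstart), depth / 2)
          if (sum(nmol) == 0) next
          wstart <- rep(if (side == "top") fstart else fend - read_length + 1L, nmol)
          reads <- emit_reads(hseq, wstart, side, read_length, prop, is_cpg_c,
                              conversion, error_rate)
          out_seq <- c(out_seq, reads)
          truth[[length(truth) + 1L]] <- data.frame(
            individual = individual, chrom = cn, start = wstart,
            strand = if (side == "top") "+" else "-", hap = hap)
        }
      }
    }
    n <- length(out_seq)
    ids <- sprintf("%s_r%07d", individual, seq_len(n))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(individual = character(0), chrom = character(0),
                 start = integer(0), strand = character(0), hap = character(0))
    truth <- cbind(id = ids, truth)
    rownames(truth) <- NULL
    list(reads = data.frame(id = ids, seq = out_seq,
                            qual = strrep("I", read_length)),
         truth = truth)
  })
}

# Vectorised molecule -> read conversion for one (chrom, haplotype, side).
emit_reads <- function(hseq, wstart, side, read_length, prop, is_cpg_c,
                       conversion, error_rate) {
  n <- length(wstart)
  raw <- substring(hseq, wstart, wstart + read_length - 1L)
  M <- str_matrix(raw, read_length)
  P <- outer(wstart, 0:(read_length - 1L), "+")
  if (side == "top") {
    target <- M == "C"
    cpg_here <- matrix(is_cpg_c[P], n)
    pm <- matrix(prop[P], n)
    converted_base <- "T"
  } else {
    target <- M == "G"
    # a G at p pairs with the CpG C at p-1 on this haplotype
    Pm1 <- pmax(P - 1L, 1L)
    cpg_here <- matrix(is_cpg_c[Pm1], n) & P > 1L
    pm <- matrix(prop[Pm1], n)
    converted_base <- "A"
  }
  pm[is.na(pm)] <- 0
  methylated <- matrix(runif(n * read_length), n) < pm & cpg_here
  convert <- target & !methylated &
    (matrix(runif(n * read_length), n) < conversion)
  M[convert] <- converted_base
  if (error_rate > 0) {
    err <- matrix(runif(n * read_length), n) < error_rate
    k <- sum(err)
    if (k) {
      cur <- M[err]
      pick <- vapply(cur, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                     character(1))
      M[err] <- pick
    }
  }
  out <- do.call(paste0, as.data.frame(M, stringsAsFactors = FALSE))
  if (side == "bottom") out <- revcomp(out)
  out
}

#' Write/read simulated reads as FASTQ
#'
#' @param reads data.frame with id, seq and qual columns.
#' @param path FASTQ file path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  # the metadata-column note from the Biostrings constructor is expected here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}
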