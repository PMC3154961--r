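#' Bisulfite-aware unique-best alignment of short reads
#'
#' Three-letter alignment at desk scale: all cytosines in the read are
#' converted to thymidines and searched against a C->T converted forward-
#' strand index; the read's reverse complement is G->A converted and searched
#' against a G->A converted index (bottom-strand placements). Candidate
#' placements are generated by exact 12-mer seeds at three offsets, which by
#' the pigeonhole principle finds every ungapped placement with at most two
#' mismatches. A read is reported only when its best-scoring placement
#' (mismatches in converted space) is strictly unique across both strands and
#' all chromosomes; ties are discarded. Mismatches are then re-annotated
#' against the unconverted reference with bisulfite masking: a forward-strand
#' T over a reference C, or a reverse-strand A (forward coordinates) over a
#' reference G, is methylation signal, not a mismatch.
#'
#' When `mappability_mask` is TRUE (default), only placements at fragment-end
#' windows whose reference sequence is itself a unique best self-alignment are
#' retained, mirroring the requirement that the reference position be the best
#' and unique alignment to itself. The mask can only remove alignments.
#'
#' @param reads data.frame with `id` and `seq` columns (or a named character
#'   vector of sequences).
#' @param ref a `synthetic_reference`.
#' @param max_mismatches maximum converted-space mismatches (default 2).
#' @param mappability_mask TRUE, FALSE, or a precomputed mask from
#'   [reference_mappability()].
#' @param read_length expected read length; reads of any other length are an
#'   input error.
#' @param fragment_range size-selection window used for the mappability mask.
#' @return data.frame of class `bisulfite_alignments`: read_id, chrom, start,
#'   end (1-based closed span of `read_length`), strand, score (converted-
#'   space mismatches), n_mismatch (masked, original space), mismatches
#'   ("offset:ref>obs" comma-joined), fwd_seq (read bases in forward
#'   orientation).
#' @export
convert_and_align <- function(reads, ref, max_mismatches = 2L,
                              mappability_mask = TRUE,
                              read_length = 36L,
                              fragment_range = c(40L, 120L)) {
  if (is.character(reads)) {
    reads <- data.frame(id = names(reads) %||% as.character(seq_along(reads)),
                        seq = unname(reads))
  }
  if (nrow(reads) == 0) stopf("no reads supplied")
  if (any(nchar(reads$seq) != read_length)) {
    stopf("all reads must have length %d", read_length)
  }
  bi <- bisulfite_index(ref, read_length)

  uniq <- unique(reads$seq)
  qct <- convert_ct(uniq)
  qga <- convert_ga(revcomp(uniq))
  hits <- align_core(qct, qga, bi, max_mismatches, read_length)

  if (!isFALSE(mappability_mask)) {
    mask <- if (isTRUE(mappability_mask)) {
      reference_mappability(ref, read_length, fragment_range, max_mismatches)
    } else mappability_mask
    keys <- paste(hits$chrom, hits$start, hits$strand)
    hits <- hits[keys %in% mask$keys, , drop = FALSE]
  }

  m <- match(reads$seq, uniq)
  take <- match(m, hits$qi)
  ok <- !is.na(take)
  hit <- hits[take[ok], , drop = FALSE]
  out <- data.frame(read_id = reads$id[ok], chrom = hit$chrom,
                    start = hit$start, end = hit$start + read_length - 1L,
                    strand = hit$strand, score = hit$score)
  out$fwd_seq <- ifelse(out$strand == "+", reads$seq[ok], revcomp(reads$seq[ok]))

  # Original-space mismatch annotation with bisulfite masking.
  refwin <- substring(ref$chromosomes[out$chrom], out$start, out$end)
  mr <- int_matrix(refwin, read_length)
  mq <- int_matrix(out$fwd_seq, read_length)
  fwd <- matrix(out$strand == "+", nrow(out), read_length)
  masked <- (fwd & mr == 67L & mq == 84L) | (!fwd & mr == 71L & mq == 65L)
  mm <- (mr != mq) & !masked
  out$n_mismatch <- as.integer(rowSums(mm))
  out$mismatches <- rep("", nrow(out))
  for (i in which(out$n_mismatch > 0)) {
    j <- which(mm[i, ])
    out$mismatches[i] <- paste(sprintf("%d:%s>%s", j,
                                       intToUtf8(mr[i, j], multiple = TRUE),
                                       intToUtf8(mq[i, j], multiple = TRUE)),
                               collapse = ",")
  }
  rownames(out) <- NULL
  class(out) <- c("bisulfite_alignments", "data.frame")
  out
}

SEED_LEN <- 12L

# Seed indexes are memoised in the reference's cache environment, so repeated
# alignment calls against the same reference pay the build cost once.
bisulfite_index <- function(ref, read_length) {
  cache <- attr(ref, "cache")
  if (!is.null(cache) && !is.null(cache$bisulfite_index)) {
    return(cache$bisulfite_index)
  }
  bi <- lapply(ref$chromosomes, function(seq) {
    ct <- convert_ct(seq)
    ga <- convert_ga(seq)
    list(ct = ct, ga = ga,
         idx_ct = kmer_index(ct), idx_ga = kmer_index(ga))
  })
  if (!is.null(cache)) cache$bisulfite_index <- bi
  bi
}

kmer_index <- function(seq) {
  L <- nchar(seq)
  env <- new.env(hash = TRUE, parent = emptyenv())
  if (L < SEED_LEN) return(env)
  starts <- seq_len(L - SEED_LEN + 1L)
  kmers <- substring(seq, starts, starts + SEED_LEN - 1L)
  list2env(split(starts, kmers), envir = env)
  env
}

# Unique-best placements for converted queries across both strand indexes.
# Returns one row per query with a strictly unique best placement.
align_core <- function(qct, qga, bi, max_mm, read_length) {
  n <- length(qct)
  offs <- seq(1L, read_length - SEED_LEN + 1L, by = SEED_LEN)
  cand <- list()
  for (cn in names(bi)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qct else qga
      env <- if (strand == "+") bi[[cn]]$idx_ct else bi[[cn]]$idx_ga
      refstr <- if (strand == "+") bi[[cn]]$ct else bi[[cn]]$ga
      Lc <- nchar(refstr)
      for (o in offs) {
        seeds <- substr(q, o, o + SEED_LEN - 1L)
        hitlist <- mget(seeds, envir = env, ifnotfound = list(NULL))
        nh <- lengths(hitlist)
        if (!sum(nh)) next
        qi <- rep(seq_len(n), nh)
        starts <- unlist(hitlist, use.names = FALSE) - o + 1L
        keep <- starts >= 1L & (starts + read_length - 1L) <= Lc
        if (!any(keep)) next
        cand[[length(cand) + 1L]] <- data.frame(
          qi = qi[keep], chrom = cn, start = starts[keep], strand = strand)
      }
    }
  }
  if (!length(cand)) {
    return(data.frame(qi = integer(0), chrom = character(0),
                      start = integer(0), strand = character(0),
                      score = integer(0)))
  }
  cc <- do.call(rbind, cand)
  cc <- cc[!duplicated(paste(cc$qi, cc$chrom, cc$start, cc$strand)), , drop = FALSE]

  cc$mm <- NA_integer_
  for (cn in unique(cc$chrom)) {
    for (strand in c("+", "-")) {
      sel <- cc$chrom == cn & cc$strand == strand
      if (!any(sel)) next
      refstr <- if (strand == "+") bi[[cn]]$ct else bi[[cn]]$ga
      q <- if (strand == "+") qct else qga
      refwin <- substring(refstr, cc$start[sel], cc$start[sel] + read_length - 1L)
      cc$mm[sel] <- string_mismatches(q[cc$qi[sel]], refwin, read_length)
    }
  }
  best <- tapply(cc$mm, cc$qi, min)
  cc$best <- best[as.character(cc$qi)]
  at_best <- cc$mm == cc$best
  n_best <- tapply(at_best, cc$qi, sum)
  cc$n_best <- n_best[as.character(cc$qi)]
  win <- cc[at_best & cc$n_best == 1L & cc$best <= max_mm, , drop = FALSE]
  data.frame(qi = win$qi, chrom = win$chrom, start = win$start,
             strand = win$strand, score = win$mm)
}

#' Reference self-uniqueness (mappability) mask over fragment-end windows
#'
#' For every sequencable end window of a size-selected MspI fragment, checks
#' that the reference-derived converted read maps back uniquely and best to
#' its own position; windows that fail are excluded from alignment reporting.
#'
#' @inheritParams convert_and_align
#' @return list with `keys` ("chrom start strand" of allowed placements) and
#'   the window table with a `mappable` flag.
#' @export
reference_mappability <- function(ref, read_length = 36L,
                                  fragment_range = c(40L, 120L),
                                  max_mismatches = 2L) {
  win <- fragment_windows(ref, read_length, fragment_range)
  if (!nrow(win)) return(list(keys = character(0), windows = win))
  bi <- bisulfite_index(ref, read_length)
  winseq <- substring(ref$chromosomes[win$chrom], win$wstart,
                      win$wstart + read_length - 1L)
  # fwd windows emit the window itself; rev windows emit its reverse
  # complement. In converted query space that is CT(win)/GA(rc(win)) for fwd
  # and CT(rc(win))/GA(win) for rev.
  read <- ifelse(win$type == "fwd", winseq, revcomp(winseq))
  qct <- convert_ct(read)
  qga <- convert_ga(revcomp(read))
  hits <- align_core(qct, qga, bi, max_mismatches, read_length)
  expected_strand <- ifelse(win$type == "fwd", "+", "-")
  ok <- logical(nrow(win))
  m <- match(seq_len(nrow(win)), hits$qi)
  found <- !is.na(m)
  ok[found] <- hits$chrom[m[found]] == win$chrom[found] &
    hits$start[m[found]] == win$wstart[found] &
    hits$strand[m[found]] == expected_strand[found]
  win$mappable <- ok
  list(keys = paste(win$chrom, win$wstart, expected_strand)[ok], windows = win)
}
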