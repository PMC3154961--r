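#' @importFrom stats anova binom.test coef cor dhyper fisher.test lm p.adjust
#'   pf phyper rbeta rbinom rnorm rpois runif sd setNames smooth.spline var
#'   wilcox.test as.dist cutree dist hclust predict rbinom quantile
#' @importFrom utils head read.delim write.table
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

# In-silico bisulfite conversions of whole strings.
convert_ct <- function(x) chartr("C", "T", x)
convert_ga <- function(x) chartr("G", "A", x)

# All start positions of a fixed motif in a single sequence (1-based).
# gregexpr() reports non-overlapping matches left-to-right, which is exact for
# motifs that cannot overlap themselves by less than their own period
# (true for "CG" and "CCGG").
motif_positions <- function(seq, motif) {
  if (is.na(seq) || nchar(seq) < nchar(motif)) return(integer(0))
  hits <- gregexpr(motif, seq, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

# Split equal-length strings into a character matrix (one row per string).
str_matrix <- function(x, width) {
  if (length(x) == 0) return(matrix(character(0), nrow = 0, ncol = width))
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         nrow = length(x), ncol = width, byrow = TRUE)
}

# Split equal-length strings into an integer (UTF-8 code) matrix.
int_matrix <- function(x, width) {
  if (length(x) == 0) return(matrix(integer(0), nrow = 0, ncol = width))
  matrix(utf8ToInt(paste(x, collapse = "")), nrow = length(x), ncol = width,
         byrow = TRUE)
}

# Hamming distances between pairs of equal-length strings (vectorised).
string_mismatches <- function(a, b, width) {
  if (length(a) == 0) return(integer(0))
  as.integer(rowSums(int_matrix(a, width) != int_matrix(b, width)))
}

# FNV-1a hash of a character scalar, as 8 hex digits (config stamping).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample()-trap-safe permutation
shuffle <- function(x) x[sample.int(length(x))]

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# Locus keys used to match SNPs/CpGs/events across samples.
pos_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
pair_key <- function(chrom, snp_pos, cpg_pos) paste(chrom, snp_pos, cpg_pos, sep = ":")
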