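#' @useDynLib polyrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Symmetric rounding used wherever fractional copy numbers or read counts
#' must become integers (abundances are counts). `round()` in R rounds half
#' to even, which would make e.g. 0.5 and 1.5 both round to different
#' parities; half-away-from-zero is the documented convention here.
#'
#' @param x numeric vector
#' @return numeric vector of integers (as doubles, to allow values > 2^31)
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

DNA_BASES_CHR <- c("A", "C", "G", "T")

#' Generate random DNA strings
#' @param n number of strings
#' @param len length of each string
#' @return character vector of length `n`
#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES_CHR, n * len, replace = TRUE), nrow = len)
  collapse_char_matrix(m)
}

# paste rows of an L x n character matrix into n strings, vectorized
collapse_char_matrix <- function(m) {
  do.call(paste0, lapply(seq_len(nrow(m)), function(i) m[i, ]))
}

#' Mutate sequences by random substitutions
#'
#' Each base is substituted independently with probability `rate`; a
#' substituted base is replaced by one of the three other bases uniformly.
#' Used both for between-copy divergence and for sequencing error.
#'
#' @param seqs character vector of equal- or unequal-length DNA strings
#' @param rate per-base substitution probability in \[0, 1\]
#' @return character vector of mutated sequences
#' @keywords internal
mutate_seqs <- function(seqs, rate) {
  if (length(seqs) == 0L || rate <= 0) return(seqs)
  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(stats::runif(length(flat)) < rate)
  if (length(hit)) {
    # replace by a uniformly chosen *different* base
    cur <- flat[hit]
    off <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(cur, DNA_BASES_CHR) - 1L + off) %% 4L + 1L
    flat[hit] <- DNA_BASES_CHR[idx]
  }
  grp <- rep.int(seq_along(seqs), lens)
  vapply(split(flat, grp), paste, character(1), collapse = "")
}

reverse_complement_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract all k-mers of a set of equal-length sequences
#' @param seqs character vector, uniform length
#' @param k k-mer size
#' @return data.table with columns read (index), pos (1-based start), kmer
#' @keywords internal
extract_kmers <- function(seqs, k) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L), k <= L)
  nw <- L - k + 1L
  n <- length(seqs)
  dt <- data.table::data.table(
    read = rep(seq_len(n), each = nw),
    pos  = rep.int(seq_len(nw), n)
  )
  dt[, kmer := substring(seqs[read], pos, pos + k - 1L)]
  dt[!grepl("N", kmer, fixed = TRUE)]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score cluster recovery against simulation truth.
#'
#' @param a,b label vectors of equal length
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}
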