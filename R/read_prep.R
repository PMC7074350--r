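#' Quality-filter and trim reads to uniform length
#'
#' Discards reads whose minimum per-base Phred score fails the quality
#' floor or which contain too many ambiguous bases, then truncates the
#' survivors to their first `target_length` bases (5' prefix); reads
#' shorter than `target_length` are discarded. Input order is preserved.
#' Stricter quality filtering is deliberately avoided: AT/GC-rich repeats
#' such as satellites tend to have lower quality scores, and harsher
#' filters bias their abundance estimates.
#'
#' @param raw a read_set with per-base qualities
#' @param min_phred quality floor; a read is discarded if any base has
#'   Phred \eqn{\le} `min_phred` (default 10). With `per_read_mean = TRUE`
#'   the rule instead applies to the read's mean quality.
#' @param max_n maximum number of N bases tolerated (default 3)
#' @param target_length uniform length after trimming (default 91)
#' @param per_read_mean apply the quality floor to the mean rather than
#'   the minimum per-base quality
#' @return a read_set of uniform length; a warning is emitted if it is
#'   empty
#' @export
preprocess_reads <- function(raw, min_phred = 10L, max_n = 3L,
                             target_length = 91L, per_read_mean = FALSE) {
  stopifnot(inherits(raw, "read_set"))
  if (length(raw) == 0L) return(raw)
  q <- if (per_read_mean) {
    vapply(raw$quality, function(s) mean(utf8ToInt(s)) - 33, numeric(1),
           USE.NAMES = FALSE)
  } else {
    min_phred(raw$quality)
  }
  keep <- q > min_phred &
    count_n(raw$sequence) <= max_n &
    nchar(raw$sequence) >= target_length
  out <- raw[keep]
  out$sequence <- substring(out$sequence, 1L, target_length)
  out$quality <- substring(out$quality, 1L, target_length)
  if (length(out) == 0L)
    warning("no reads survived quality filtering and trimming")
  out
}

#' Subsample a read set to a fixed genome proportion
#'
#' Draws `round(proportion * c_value_bp / read_length)` reads uniformly
#' without replacement, making read counts comparable across genomes of
#' different sizes (the fixed-genome-proportion convention).
#'
#' @param rs a preprocessed (uniform-length) read_set
#' @param c_value_bp the species' 1C genome size in bp
#' @param proportion genome proportion (default 0.02)
#' @param seed integer seed; the same seed selects the same reads
#' @return a read_set with the target number of reads
#' @export
subsample_reads <- function(rs, c_value_bp, proportion = 0.02, seed = 1L) {
  stopifnot(inherits(rs, "read_set"), c_value_bp > 0, proportion > 0)
  rl <- read_length(rs)
  n <- reads_for_proportion(c_value_bp, proportion, rl)
  if (n == 0) {
    warning("requested subsample size is zero reads")
    return(rs[integer(0)])
  }
  if (n > length(rs))
    stop(sprintf(
      "subsample needs %d reads but only %d are available (short by %d)",
      n, length(rs), n - length(rs)))
  idx <- with_seed(seed, sort(sample.int(length(rs), n)))
  rs[idx]
}

#' Prefix read identifiers with a five-letter species code
#'
#' Species-tagged identifiers let reads from several species be pooled
#' for comparative clustering and attributed back afterwards.
#'
#' @param rs a read_set
#' @param code five-letter species code (`^[A-Za-z]{5}$`)
#' @return the read_set with every read_id prefixed `code` + "_" and
#'   `species_code` set
#' @export
tag_species <- function(rs, code) {
  stopifnot(inherits(rs, "read_set"))
  validate_species_code(code)
  rs$read_id <- if (length(rs)) paste0(code, "_", rs$read_id) else character(0)
  rs$species_code <- code
  rs
}

#' Species code carried by a pooled read identifier
#' @param read_id character vector of tagged read ids
#' @return character vector of five-letter prefixes
#' @keywords internal
species_prefix <- function(read_id) substr(read_id, 1L, 5L)
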