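#' ReadSet: a collection of uniform-provenance sequencing reads
#'
#' Lightweight container for single-end reads of one species/accession:
#' read identifiers, sequences, per-base Phred qualities (stored as
#' Sanger Phred+33 strings), an optional five-letter species code, and an
#' optional truth label (`family`) recording which simulated repeat family
#' each read was drawn from (NA for reads of unknown origin, e.g. real
#' data; `"single_copy"` for background reads).
#'
#' @param read_id character vector of unique read identifiers
#' @param sequence character vector of DNA sequences (A/C/G/T/N)
#' @param quality character vector of Phred+33 quality strings, same
#'   lengths as `sequence`
#' @param species_code NULL or a five-letter species code
#' @param family optional character vector of truth labels, recycled NA
#' @return an object of class `read_set`
#' @export
read_set <- function(read_id, sequence, quality,
                     species_code = NULL, family = NULL) {
  read_id <- as.character(read_id)
  sequence <- as.character(sequence)
  quality <- as.character(quality)
  n <- length(read_id)
  if (length(sequence) != n || length(quality) != n)
    stop("read_id, sequence and quality must have equal length")
  if (any(nchar(sequence) != nchar(quality)))
    stop("each read's quality string must match its sequence length")
  if (anyDuplicated(read_id))
    stop("read identifiers must be unique")
  if (!is.null(species_code)) validate_species_code(species_code)
  if (is.null(family)) family <- rep(NA_character_, n)
  if (length(family) != n) stop("family must match the number of reads")
  structure(
    list(read_id = read_id, sequence = sequence, quality = quality,
         species_code = species_code, family = as.character(family)),
    class = "read_set"
  )
}

validate_species_code <- function(code) {
  if (!is.character(code) || length(code) != 1L || !grepl("^[A-Za-z]{5}$", code))
    stop("species code must be exactly five letters (A-Za-z), got: ",
         deparse(code))
  invisible(code)
}

#' @export
length.read_set <- function(x) length(x$read_id)

#' @export
print.read_set <- function(x, ...) {
  lens <- unique(nchar(x$sequence))
  cat(sprintf(
    "read_set: %d reads%s, length %s\n",
    length(x),
    if (is.null(x$species_code)) "" else paste0(" [", x$species_code, "]"),
    if (length(lens) == 0) "-" else if (length(lens) == 1) lens else
      paste0(min(lens), "-", max(lens))
  ))
  invisible(x)
}

#' Subset a read set by index
#' @param x a read_set
#' @param i integer or logical index
#' @param ... unused
#' @export
`[.read_set` <- function(x, i, ...) {
  read_set(x$read_id[i], x$sequence[i], x$quality[i],
           species_code = x$species_code, family = x$family[i])
}

#' Uniform read length of a read set
#' @param rs a read_set
#' @return integer read length; errors if lengths are not uniform
#' @export
read_length <- function(rs) {
  lens <- unique(nchar(rs$sequence))
  if (length(lens) != 1L)
    stop("read set does not have uniform read length (preprocess first)")
  as.integer(lens)
}

phred_string <- function(phred, len) {
  strrep(rawToChar(as.raw(phred + 33L)), len)
}

min_phred <- function(quality) {
  vapply(quality, function(q) {
    if (nchar(q) == 0L) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

count_n <- function(sequence) {
  nchar(sequence) - nchar(gsub("N", "", sequence, fixed = TRUE))
}

#' Read a FASTQ file into a read_set
#'
#' @param path FASTQ path (gzip-transparent)
#' @param species_code optional five-letter code to attach
#' @return a read_set
#' @export
read_fastq <- function(path, species_code = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  read_set(names(x), as.character(x), qual, species_code = species_code)
}

#' Write a read_set to FASTQ (Sanger Phred+33)
#'
#' @param rs a read_set
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fastq <- function(rs, path) {
  x <- Biostrings::DNAStringSet(rs$sequence)
  names(x) <- rs$read_id
  q <- Biostrings::BStringSet(rs$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write the simulation truth table for a read_set
#'
#' Three-column TSV: read_id, species_code, family_id. Reads from the
#' single-copy background carry family_id `"single_copy"`.
#'
#' @param rs a read_set with truth labels
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_truth_tsv <- function(rs, path) {
  df <- data.frame(
    read_id = rs$read_id,
    species_code = rs$species_code %||% NA_character_,
    family_id = rs$family,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
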