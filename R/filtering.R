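#' Describe a polyploidy cross design
#'
#' Names which species code plays which role: maternal diploid, paternal
#' diploid, and the allotetraploid derived from them.
#'
#' @param maternal_code,paternal_code,tetraploid_code distinct
#'   five-letter species codes
#' @return an object of class `cross_design`
#' @export
cross_design <- function(maternal_code, paternal_code, tetraploid_code) {
  codes <- c(maternal_code, paternal_code, tetraploid_code)
  for (code in codes) validate_species_code(code)
  if (anyDuplicated(codes)) stop("cross design codes must be distinct")
  structure(list(maternal = maternal_code, paternal = paternal_code,
                 tetraploid = tetraploid_code),
            class = "cross_design")
}

check_design <- function(table, design) {
  codes <- attr(table, "species_codes")
  missing <- setdiff(unlist(design[c("maternal", "paternal", "tetraploid")]),
                     codes)
  if (length(missing))
    stop("design code(s) not present in the cluster table: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# canonical (strand-collapsed) k-mer set of a set of sequences
canonical_kmer_set <- function(seqs, k) {
  seqs <- toupper(as.character(seqs))
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    st <- seq_len(n - k + 1L)
    substring(s, st, st + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (!length(kmers)) return(character(0))
  unique(pmin(kmers, reverse_complement_chr(kmers)))
}

#' Flag contaminant clusters by k-mer sharing with reference sequences
#'
#' A read matches the contaminant references iff it shares at least one
#' canonical (strand-collapsed) k-mer with any reference sequence (e.g.
#' organellar genomes, known artefacts). A cluster is flagged iff at
#' least `min_fraction` of its member reads match. Flags are recorded in
#' the `contaminant` column; nothing is removed at this stage.
#'
#' @param table a cluster_table with membership (from [tabulate_clusters()])
#' @param reads the pooled read_set the clusters were built from
#' @param contaminant_refs FASTA path, `DNAStringSet`, or character
#'   vector of reference sequences; may be empty (no flags)
#' @param k k-mer length (default 17)
#' @param min_fraction matching-read fraction at or above which a
#'   cluster is flagged (default 0.5)
#' @param members optional membership list; defaults to the table's own
#' @return the cluster_table with the `contaminant` column filled in
#' @export
flag_contaminants <- function(table, reads, contaminant_refs, k = 17L,
                              min_fraction = 0.5, members = NULL) {
  stopifnot(inherits(table, "cluster_table"), inherits(reads, "read_set"))
  members <- members %||% cluster_members(table)
  if (is.null(members))
    stop("cluster membership is required to flag contaminants")
  refs <- if (is.character(contaminant_refs) && length(contaminant_refs) == 1 &&
              file.exists(contaminant_refs)) {
    as.character(Biostrings::readDNAStringSet(contaminant_refs))
  } else if (methods::is(contaminant_refs, "DNAStringSet")) {
    as.character(contaminant_refs)
  } else {
    as.character(contaminant_refs)
  }
  ref_kmers <- canonical_kmer_set(refs, k)
  table$contaminant <- FALSE
  table$contaminant_fraction <- 0
  if (length(ref_kmers) == 0L) return(table)

  hit_by_read <- function(seqs) {
    vapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(FALSE)
      st <- seq_len(n - k + 1L)
      km <- substring(s, st, st + k - 1L)
      km <- km[!grepl("[^ACGT]", km)]
      if (!length(km)) return(FALSE)
      any(pmin(km, reverse_complement_chr(km)) %in% ref_kmers)
    }, logical(1), USE.NAMES = FALSE)
  }
  idx <- stats::setNames(seq_along(reads$read_id), reads$read_id)
  for (i in seq_len(nrow(table))) {
    ids <- members[[table$cluster_id[i]]]
    hits <- hit_by_read(reads$sequence[idx[ids]])
    frac <- mean(hits)
    table$contaminant_fraction[i] <- frac
    table$contaminant[i] <- frac >= min_fraction
  }
  table
}

#' Filter a cluster table for comparative analysis
#'
#' Applies, in order: removal of flagged contaminant clusters; a
#' per-species presence threshold (a species "has" a cluster iff its
#' read count is at least `min_reads`); removal of species-specific
#' clusters (present in fewer than two species); and removal of clusters
#' not present in the tetraploid. Retained clusters keep their original
#' counts and are marked with which regressions they can enter
#' (`usable`: "both", "maternal_only", "paternal_only", or, with
#' `keep_parents_only = TRUE`, "deviation_only" for clusters present in
#' both parents but lost from the tetraploid — total loss of a parental
#' repeat is itself a deviation signal). Every removal is logged with
#' exactly one reason (attribute `filter_log`).
#'
#' @param table a cluster_table (contaminant flags computed, or all
#'   FALSE)
#' @param design a [cross_design()]
#' @param min_reads per-species presence threshold (default 10)
#' @param require_all_species if TRUE, keep only clusters present in all
#'   three species (the strict reading of the presence rule)
#' @param keep_parents_only retain both-parent clusters missing from the
#'   tetraploid, usable for deviation curves only
#' @return the filtered cluster_table with `present_in` and `usable`
#'   columns and a `filter_log` attribute
#' @export
apply_filters <- function(table, design, min_reads = 10L,
                          require_all_species = FALSE,
                          keep_parents_only = FALSE) {
  stopifnot(inherits(table, "cluster_table"), inherits(design, "cross_design"))
  check_design(table, design)
  m <- table[[design$maternal]]
  p <- table[[design$paternal]]
  t <- table[[design$tetraploid]]
  pres_m <- m >= min_reads
  pres_p <- p >= min_reads
  pres_t <- t >= min_reads
  n_pres <- pres_m + pres_p + pres_t

  reason <- rep(NA_character_, nrow(table))
  reason[table$contaminant] <- "contaminant"
  todo <- is.na(reason)
  if (require_all_species) {
    reason[todo & n_pres < 3] <- ifelse(
      n_pres[todo & n_pres < 3] < 2, "species_specific", "absent_in_some_species")
  } else {
    reason[todo & n_pres < 2] <- "species_specific"
    todo <- is.na(reason)
    drop_no_tet <- todo & !pres_t &
      !(keep_parents_only & pres_m & pres_p)
    reason[drop_no_tet] <- "absent_in_tetraploid"
  }

  keep <- is.na(reason)
  log <- data.frame(cluster_id = table$cluster_id[!keep],
                    reason = reason[!keep], stringsAsFactors = FALSE)
  out <- table[keep, , drop = FALSE]
  pm <- pres_m[keep]; pp <- pres_p[keep]; pt <- pres_t[keep]
  out$present_in <- vapply(seq_len(nrow(out)), function(i) {
    paste(c(design$maternal, design$paternal, design$tetraploid)[
      c(pm[i], pp[i], pt[i])], collapse = ",")
  }, character(1))
  out$usable <- ifelse(!pt, "deviation_only",
                ifelse(pm & pp, "both",
                ifelse(pm, "maternal_only",
                ifelse(pp, "paternal_only", "deviation_only"))))
  members <- cluster_members(table)
  structure(as.data.frame(out, stringsAsFactors = FALSE),
            species_codes = attr(table, "species_codes"),
            members = if (!is.null(members)) members[out$cluster_id],
            filter_log = log,
            min_reads = min_reads,
            class = c("cluster_table", "data.frame"))
}

#' Removal log of a filtered cluster table
#' @param table a cluster_table returned by [apply_filters()]
#' @return data.frame with columns cluster_id, reason
#' @export
filter_log <- function(table) attr(table, "filter_log")
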