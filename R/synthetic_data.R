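#' Construct a simulated genome specification
#'
#' A `genome_spec` describes one haploid (1C) genome as a set of repeat
#' families embedded in a single-copy background. Each family has a
#' consensus sequence (its unit), a copy number per 1C, and a per-copy
#' divergence: the substitution rate separating individual genomic copies
#' from the family consensus. The tetraploid produced by
#' [apply_inheritance()] additionally carries a `haplotype` column marking
#' which parental subgenome each family row descends from.
#'
#' @param species_code five-letter species/accession code
#' @param c_value_bp 1C genome size in bp (positive)
#' @param families data.frame with columns `family_id`, `consensus`,
#'   `copies_per_1C`, `per_copy_divergence` (and optionally `haplotype`)
#' @param single_copy_fraction proportion of the genome that is
#'   single-copy background, in \[0, 1\]
#' @return an object of class `genome_spec`
#' @export
genome_spec <- function(species_code, c_value_bp, families,
                        single_copy_fraction = 0.3) {
  validate_species_code(species_code)
  c_value_bp <- as.numeric(c_value_bp)
  stopifnot(length(c_value_bp) == 1L, c_value_bp > 0,
            single_copy_fraction >= 0, single_copy_fraction <= 1)
  req <- c("family_id", "consensus", "copies_per_1C", "per_copy_divergence")
  if (!all(req %in% names(families)))
    stop("families must have columns: ", paste(req, collapse = ", "))
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  if (nrow(families)) {
    stopifnot(all(families$copies_per_1C >= 0),
              all(families$per_copy_divergence >= 0),
              all(families$per_copy_divergence <= 0.3))
    if (any(grepl("[^ACGT]", families$consensus)))
      stop("family consensus sequences may contain only A/C/G/T")
  }
  families$unit_length <- nchar(families$consensus)
  rep_bp <- sum(families$copies_per_1C * families$unit_length)
  if (rep_bp > c_value_bp)
    stop(sprintf("total repeat bp (%.0f) exceeds 1C genome size (%.0f)",
                 rep_bp, c_value_bp))
  structure(
    list(species_code = species_code, c_value_bp = c_value_bp,
         families = families, single_copy_fraction = single_copy_fraction),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(
    "genome_spec [%s]: 1C = %.3g bp, %d family rows (%d families), repeat fraction %.2f\n",
    x$species_code, x$c_value_bp, nrow(x$families),
    length(unique(x$families$family_id)),
    sum(x$families$copies_per_1C * x$families$unit_length) / x$c_value_bp))
  invisible(x)
}

#' Per-family copy numbers of a genome
#'
#' Aggregates copy numbers over subgenome haplotypes, so for a tetraploid
#' the value for family f is the total copy number across both subgenomes.
#'
#' @param genome a genome_spec
#' @return named numeric vector, names are family ids
#' @export
family_abundance <- function(genome) {
  if (nrow(genome$families) == 0L) return(stats::setNames(numeric(0), character(0)))
  s <- tapply(genome$families$copies_per_1C, genome$families$family_id, sum)[
    unique(genome$families$family_id)]
  stats::setNames(as.numeric(s), names(s))
}

#' Specify a tetraploid inheritance model
#'
#' Three regimes for how per-family repeat abundance in the tetraploid
#' relates to the parental abundances, emulating the empirical spectrum
#' from near-additivity through genome upsizing to downsizing:
#' \describe{
#'   \item{additive}{t_f = m_f + p_f (the strict-additivity null).}
#'   \item{parent_bias}{one parent's contribution is multiplied by
#'     `bias_rho` before summing: t_f = m_f + round(bias_rho * p_f) for
#'     `biased_parent = "paternal"` (the direction the
#'     nuclear-cytoplasmic interaction hypothesis predicts, rho < 1).}
#'   \item{size_dependent}{families whose parental sum reaches
#'     `size_threshold` copies are scaled by `size_factor`
#'     (amplification for factor > 1, deletion for factor < 1); smaller
#'     families stay additive.}
#' }
#' All rounding is half-away-from-zero, since abundances are counts.
#'
#' @param mode one of "additive", "parent_bias", "size_dependent"
#' @param bias_rho non-negative multiplier (parent_bias mode)
#' @param biased_parent "paternal" or "maternal" (parent_bias mode)
#' @param size_threshold copy-number cutoff (size_dependent mode)
#' @param size_factor non-negative multiplier above the cutoff
#' @return an object of class `inheritance_model`
#' @export
inheritance_model <- function(mode = c("additive", "parent_bias", "size_dependent"),
                              bias_rho = 1, biased_parent = c("paternal", "maternal"),
                              size_threshold = Inf, size_factor = 1) {
  mode <- match.arg(mode)
  biased_parent <- match.arg(biased_parent)
  stopifnot(bias_rho >= 0, size_factor >= 0, size_threshold >= 0)
  structure(list(mode = mode, bias_rho = bias_rho, biased_parent = biased_parent,
                 size_threshold = size_threshold, size_factor = size_factor),
            class = "inheritance_model")
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bounded power-law copy numbers on [kmin, kmax]: floored bounded Pareto
rpowerlaw <- function(n, alpha, kmax, kmin = 1) {
  stopifnot(alpha > 1, kmax >= kmin, kmin >= 1)
  u <- stats::runif(n)
  a1 <- 1 - alpha
  x <- kmin * (1 - u * (1 - ((kmax + 1) / kmin)^a1))^(1 / a1)
  pmin(floor(x), kmax)
}

#' Simulate a pair of diploid progenitor genomes
#'
#' Draws a shared set of repeat families with heavy-tailed (bounded
#' power-law) copy numbers, then derives the two parents by (i)
#' independently perturbing each family's copy number per parent
#' (lognormal multiplicative noise, rounded to counts) and (ii) diverging
#' the family consensus sequences symmetrically so the two parents'
#' consensuses differ at rate `divergence`. If the drawn repeat content
#' would exceed the genome's repeat budget
#' `(1 - single_copy_fraction) * c_value_bp`, copy numbers are rescaled
#' proportionally (with a message) rather than silently overflowing.
#'
#' @param n_families number of shared repeat families
#' @param abundance_exponent power-law exponent (> 1) for copy numbers
#' @param divergence consensus substitution divergence between the two
#'   parents, in \[0, 0.3\]
#' @param c_value_bp 1C genome size in bp (both parents)
#' @param seed integer seed; parent-specific sub-seeds derive from it
#' @param unit_length repeat unit (consensus) length in bp
#' @param per_copy_divergence within-family divergence of genomic copies
#'   from their consensus
#' @param single_copy_fraction single-copy proportion of each genome
#' @param perturb_sd sd of the lognormal copy-number perturbation
#' @param min_copies,max_copies support bounds of the copy-number power
#'   law; `max_copies` defaults to the whole-genome bound
#'   `c_value_bp / unit_length`. A floor above 1 emulates the
#'   abundant-family regime in which every family is deep enough to form
#'   a well-sampled cluster (used by the calibration experiments).
#' @param codes five-letter codes for (maternal, paternal)
#' @param maternal_seed,paternal_seed optional explicit perturbation
#'   seeds; setting both equal makes the parents' abundances identical
#' @return list with elements `maternal` and `paternal` (genome_spec)
#' @export
simulate_parents <- function(n_families, abundance_exponent, divergence,
                             c_value_bp, seed,
                             unit_length = 500L,
                             per_copy_divergence = 0.02,
                             single_copy_fraction = 0.3,
                             perturb_sd = 0.25,
                             min_copies = 1, max_copies = NULL,
                             codes = c("MATER", "PATER"),
                             maternal_seed = NULL, paternal_seed = NULL) {
  stopifnot(n_families >= 0, abundance_exponent > 1,
            divergence >= 0, divergence <= 0.3, c_value_bp > 0)
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  maternal_seed <- maternal_seed %||% sub[2]
  paternal_seed <- paternal_seed %||% sub[3]

  kmax <- min(max_copies %||% Inf, max(1, floor(c_value_bp / unit_length)))
  base <- with_seed(sub[1], list(
    copies = if (n_families > 0)
      rpowerlaw(n_families, abundance_exponent, kmax, kmin = min_copies)
    else numeric(0),
    consensus = random_dna(n_families, unit_length)
  ))
  fam_ids <- if (n_families > 0) sprintf("FAM%03d", seq_len(n_families)) else character(0)

  budget <- (1 - single_copy_fraction) * c_value_bp
  one_parent <- function(pseed, code) {
    copies <- with_seed(pseed, {
      cp <- round_half_away(base$copies *
                              exp(stats::rnorm(n_families, 0, perturb_sd)))
      pmax(cp, 0)
    })
    # consensus divergence is split symmetrically between the parents
    cons <- with_seed(pseed + 1L, mutate_seqs(base$consensus, divergence / 2))
    rep_bp <- sum(copies * unit_length)
    if (rep_bp > budget) {
      scale <- budget / rep_bp
      copies <- floor(copies * scale)
      message(sprintf(
        "[%s] repeat content %.0f bp exceeds budget %.0f bp; copy numbers rescaled by %.3f",
        code, rep_bp, budget, scale))
    }
    genome_spec(
      code, c_value_bp,
      data.frame(family_id = fam_ids, consensus = cons,
                 copies_per_1C = copies,
                 per_copy_divergence = rep(per_copy_divergence, n_families),
                 stringsAsFactors = FALSE),
      single_copy_fraction = single_copy_fraction
    )
  }
  list(maternal = one_parent(maternal_seed, codes[1]),
       paternal = one_parent(paternal_seed, codes[2]))
}

#' Derive a tetraploid genome from two parents under an inheritance model
#'
#' Takes the union of the parental family-id namespaces (a family absent
#' from one parent contributes zero copies) and sets the tetraploid's
#' per-family copy number according to the model; see
#' [inheritance_model()]. The tetraploid keeps both parental consensus
#' variants of each family as separate subgenome rows (`haplotype`
#' column), so simulated tetraploid reads carry subgenome-specific
#' sequence just as real allopolyploid reads do. The tetraploid 1C value
#' is recomputed as the parental single-copy content plus the inherited
#' repeat content.
#'
#' @param maternal,paternal genome_spec objects sharing a family-id
#'   namespace
#' @param model an [inheritance_model()]
#' @param code five-letter code for the tetraploid
#' @return a genome_spec with per-haplotype family rows
#' @export
apply_inheritance <- function(maternal, paternal, model, code = "TETRA") {
  stopifnot(inherits(maternal, "genome_spec"), inherits(paternal, "genome_spec"),
            inherits(model, "inheritance_model"))
  fm <- maternal$families
  fp <- paternal$families
  shared <- intersect(fm$family_id, fp$family_id)
  mism <- shared[fm$unit_length[match(shared, fm$family_id)] !=
                   fp$unit_length[match(shared, fp$family_id)]]
  if (length(mism))
    stop("unit_length mismatch between parents for family: ",
         paste(mism, collapse = ", "))

  ids <- union(fm$family_id, fp$family_id)
  m <- stats::setNames(rep(0, length(ids)), ids)
  p <- m
  m[fm$family_id] <- fm$copies_per_1C
  p[fp$family_id] <- fp$copies_per_1C

  # target totals per family under the model
  t_tot <- switch(model$mode,
    additive = m + p,
    parent_bias = if (model$biased_parent == "paternal")
      m + round_half_away(model$bias_rho * p)
    else round_half_away(model$bias_rho * m) + p,
    size_dependent = {
      s <- m + p
      ifelse(s >= model$size_threshold, round_half_away(model$size_factor * s), s)
    }
  )
  # split the total back into subgenome rows
  m_new <- switch(model$mode,
    additive = m,
    parent_bias = if (model$biased_parent == "maternal") t_tot - p else m,
    size_dependent = pmin(round_half_away(t_tot * ifelse(m + p > 0, m / (m + p), 0)),
                          t_tot)
  )
  p_new <- t_tot - m_new
  stopifnot(all(m_new >= 0), all(p_new >= 0))

  row_for <- function(fam, which_parent, copies) {
    src <- if (which_parent == "maternal") fm else fp
    i <- match(fam, src$family_id)
    keep <- !is.na(i) & copies[fam] > 0
    if (!any(keep)) return(NULL)
    out <- src[i[keep], , drop = FALSE]
    out$copies_per_1C <- unname(copies[fam][keep])
    out$haplotype <- which_parent
    out
  }
  fams <- rbind(row_for(ids, "maternal", m_new), row_for(ids, "paternal", p_new))
  if (is.null(fams))
    fams <- data.frame(family_id = character(0), consensus = character(0),
                       copies_per_1C = numeric(0), per_copy_divergence = numeric(0),
                       unit_length = integer(0), haplotype = character(0))
  rownames(fams) <- NULL

  single_bp <- maternal$single_copy_fraction * maternal$c_value_bp +
    paternal$single_copy_fraction * paternal$c_value_bp
  rep_bp <- sum(fams$copies_per_1C * fams$unit_length)
  c_value <- single_bp + rep_bp
  genome_spec(code, c_value, fams[setdiff(names(fams), "unit_length")],
              single_copy_fraction = single_bp / c_value)
}

#' Number of reads at a fixed genome proportion
#'
#' Sampling reads whose total bases equal `proportion` of the 1C genome
#' size makes read counts comparable across genomes of different sizes.
#'
#' @param c_value_bp 1C genome size in bp
#' @param proportion genome proportion (default 0.02)
#' @param read_length read length in bp (default 91)
#' @return integer read count, rounded half away from zero
#' @export
reads_for_proportion <- function(c_value_bp, proportion = 0.02, read_length = 91L) {
  round_half_away(proportion * c_value_bp / read_length)
}

# sampling probabilities over family rows + single-copy background
source_probs <- function(genome) {
  fams <- genome$families
  p_fam <- if (nrow(fams)) fams$copies_per_1C * fams$unit_length / genome$c_value_bp
           else numeric(0)
  stopifnot(sum(p_fam) <= 1 + 1e-9)
  c(p_fam, max(0, 1 - sum(p_fam)))
}

#' Simulate shotgun reads from a genome at a fixed genome proportion
#'
#' Emits `round(proportion * c_value_bp / read_length)` reads. Each read
#' is drawn wholly within a single repeat copy or the single-copy
#' background (junction reads are not simulated, keeping the family
#' ground truth unambiguous): a source row is chosen with probability
#' proportional to its genomic bp, a start position uniformly within the
#' unit, the source copy's sequence is materialized by mutating the
#' consensus window at the family's per-copy divergence, and sequencing
#' error adds substitutions at `error_rate`. Base qualities are a
#' constant placeholder Phred 35. Background reads are uniform random
#' DNA, labeled `"single_copy"` in the truth.
#'
#' @param genome a genome_spec
#' @param proportion genome proportion in (0, 1]
#' @param read_length read length in bp; must not exceed any family's
#'   unit length
#' @param error_rate per-base sequencing substitution rate
#' @param seed integer seed; a fixed seed reproduces the read set exactly
#' @return a read_set with truth labels
#' @export
generate_reads <- function(genome, proportion = 0.02, read_length = 91L,
                           error_rate = 0.01, seed = 1L) {
  stopifnot(inherits(genome, "genome_spec"), proportion > 0, proportion <= 1)
  fams <- genome$families
  if (nrow(fams) && read_length > min(fams$unit_length))
    stop("read_length exceeds the unit length of at least one family")
  n <- reads_for_proportion(genome$c_value_bp, proportion, read_length)
  if (n < 1)
    stop(sprintf("proportion x genome size (%.1f bp) is below one read length",
                 proportion * genome$c_value_bp))

  with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n, source_probs(genome)))
    nf <- nrow(fams)
    seqs <- character(0); fam_lab <- character(0)
    if (nf) {
      per_row <- counts[seq_len(nf)]
      row_idx <- rep.int(seq_len(nf), per_row)
      if (length(row_idx)) {
        start <- floor(stats::runif(length(row_idx)) *
                         (fams$unit_length[row_idx] - read_length + 1)) + 1
        seqs <- substring(fams$consensus[row_idx], start, start + read_length - 1)
        # per-copy divergence then sequencing error, both substitution-only
        div <- fams$per_copy_divergence[row_idx]
        for (d in unique(div[div > 0])) {
          sel <- which(div == d)
          seqs[sel] <- mutate_seqs(seqs[sel], d)
        }
        fam_lab <- fams$family_id[row_idx]
      }
    }
    n_bg <- counts[length(counts)]
    if (n_bg > 0) {
      seqs <- c(seqs, random_dna(n_bg, read_length))
      fam_lab <- c(fam_lab, rep("single_copy", n_bg))
    }
    if (error_rate > 0) seqs <- mutate_seqs(seqs, error_rate)
    read_set(
      read_id = sprintf("r%07d", seq_along(seqs)),
      sequence = seqs,
      quality = rep(phred_string(35L, read_length), length(seqs)),
      species_code = genome$species_code,
      family = fam_lab
    )
  })
}

#' Simulate a per-family cluster table directly at the count level
#'
#' Emulates the full pipeline (fixed-proportion read sampling followed by
#' perfect per-family clustering) without generating sequences: for each
#' species, read counts over repeat families and the single-copy
#' background are drawn from one multinomial with bp-proportional
#' probabilities, exactly the distribution [generate_reads()] induces.
#' Background reads are discarded (they do not form clusters). This is
#' the fast route used for statistical calibration experiments where
#' sequence-level clustering noise is not the object of study.
#'
#' @param maternal,paternal,tetraploid genome_spec objects
#' @param proportion genome proportion (default 0.02)
#' @param read_length read length in bp (default 91)
#' @param seed integer seed
#' @return a [cluster_table()] whose rows are true repeat families,
#'   with a `family_id` column retained as truth
#' @export
simulate_cluster_table <- function(maternal, paternal, tetraploid,
                                   proportion = 0.02, read_length = 91L,
                                   seed = 1L) {
  genomes <- list(maternal, paternal, tetraploid)
  codes <- vapply(genomes, function(g) g$species_code, character(1))
  if (anyDuplicated(codes)) stop("species codes must be distinct")
  fam_ids <- Reduce(union, lapply(genomes, function(g) g$families$family_id))
  counts <- matrix(0, nrow = length(fam_ids), ncol = 3,
                   dimnames = list(fam_ids, codes))
  with_seed(seed, {
    for (j in seq_along(genomes)) {
      g <- genomes[[j]]
      n <- reads_for_proportion(g$c_value_bp, proportion, read_length)
      draw <- as.vector(stats::rmultinom(1, n, source_probs(g)))
      nf <- nrow(g$families)
      if (nf) {
        per_fam <- tapply(draw[seq_len(nf)], g$families$family_id, sum)
        counts[names(per_fam), j] <- per_fam
      }
    }
  })
  df <- data.frame(family_id = fam_ids, counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[rowSums(df[codes]) > 0, , drop = FALSE]
  as_cluster_table(df, species_codes = codes)
}
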