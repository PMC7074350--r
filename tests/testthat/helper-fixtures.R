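# Shared fixtures and independent oracles used across the suite.

with_seed <- polyrep:::with_seed
random_dna <- polyrep:::random_dna

# A genome of equally abundant planted families: the standard scenario
# for cluster-recovery checks (10 families x 1500 copies of a 300 bp
# unit in a 5.46 Mbp genome => ~1200 reads at the 2% proportion, ~80%
# of them from repeat families; the short unit keeps the positional
# read-overlap chain densely connected).
planted_genome <- function(n_fam = 10L, copies = 1500, unit = 300L,
                           c_value = 5.46e6, per_copy_divergence = 0.025,
                           seed = 11L, code = "AAAAA") {
  fams <- with_seed(seed, data.frame(
    family_id = sprintf("FAM%02d", seq_len(n_fam)),
    consensus = random_dna(n_fam, unit),
    copies_per_1C = copies,
    per_copy_divergence = per_copy_divergence,
    stringsAsFactors = FALSE))
  genome_spec(code, c_value, fams, single_copy_fraction = 0.15)
}

# quick read_set construction with uniform quality
mk_reads <- function(seqs, ids = sprintf("r%03d", seq_along(seqs)),
                     phred = 35L, code = NULL) {
  qual <- vapply(nchar(seqs),
                 function(l) strrep(rawToChar(as.raw(phred + 33L)), l),
                 character(1))
  read_set(ids, seqs, qual, species_code = code)
}

# cluster table straight from per-species count columns
mk_table <- function(m, p, t, codes = c("MATER", "PATER", "TETRA")) {
  df <- data.frame(m, p, t)
  names(df) <- codes
  as_cluster_table(df, codes)
}

std_design <- function() cross_design("MATER", "PATER", "TETRA")

# random deviation-record datasets for regression oracle checks
rand_records <- function(n, seed, noise = 0.3) {
  with_seed(seed, {
    m <- floor(exp(runif(n, log(15), log(3000))))
    p <- floor(exp(runif(n, log(15), log(3000))))
    t <- pmax(10, round((m + p) * exp(rnorm(n, 0, noise))))
    data.frame(cluster_id = sprintf("CL%03d", 1:n), m = m, p = p, t = t,
               E = m + p, D = t - m - p)
  })
}

# --- independent edge oracle -------------------------------------------------
# Brute-force realization of the full edge rule on ALL pairs: the
# distinct-shared-k-mer candidacy by direct set intersection, and the
# overlap identity by one-hot matrix products over every admissible
# shift. Shares no code with the package's k-mer index or C++ scan.

onehot_bases <- function(seqs) {
  ch <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cbind((ch == "A") * 1, (ch == "C") * 1, (ch == "G") * 1, (ch == "T") * 1)
}

oracle_edges <- function(seqs, k = 17L, min_identity = 0.9,
                         min_coverage = 0.55, min_shared = 2L) {
  L <- nchar(seqs[1])
  n <- length(seqs)
  min_ov <- ceiling(min_coverage * L - 1e-9)
  max_shift <- L - min_ov
  best <- matrix(-1, n, n)
  for (d in 0:max_shift) {
    ov <- L - d
    X <- onehot_bases(substring(seqs, 1 + d, L))
    Y <- onehot_bases(substring(seqs, 1, ov))
    M <- tcrossprod(X, Y)
    id <- M / ov
    w <- ifelse(id >= min_identity, id * (ov / L), -1)
    best <- pmax(best, w, t(w))
  }
  kml <- lapply(seqs, function(s) unique(substring(s, 1:(L - k + 1), k:L)))
  cand <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cand[i, j] <- length(intersect(kml[[i]], kml[[j]])) >= min_shared
    }
  }
  idx <- which(best >= 0 & cand & upper.tri(best), arr.ind = TRUE)
  data.frame(a = idx[, 1], b = idx[, 2], w = best[idx])
}

# edge table of a read_graph as indices into a reference id ordering
graph_edge_keys <- function(g, ref_ids) {
  a <- match(g$edges$from, ref_ids)
  b <- match(g$edges$to, ref_ids)
  data.frame(a = pmin(a, b), b = pmax(a, b), w = g$edges$weight)
}

# closed-form adjusted Rand index (pair-counting formula), used as the
# independent check of the package's partition-agreement scoring
ari_formula <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# map a partition (list of id vectors) to a named membership vector
partition_membership <- function(partition) {
  stats::setNames(rep(seq_along(partition), lengths(partition)),
                  unlist(partition))
}
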