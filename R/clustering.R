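#' Pool species-tagged read sets for comparative clustering
#'
#' @param ... read_set objects that have been through [tag_species()]
#' @return one read_set holding all reads (species_code unset)
#' @export
pool_reads <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "read_set")))
  for (rs in sets) {
    if (is.null(rs$species_code))
      stop("all read sets must be species-tagged before pooling")
  }
  read_set(
    read_id = unlist(lapply(sets, `[[`, "read_id")),
    sequence = unlist(lapply(sets, `[[`, "sequence")),
    quality = unlist(lapply(sets, `[[`, "quality")),
    family = unlist(lapply(sets, `[[`, "family"))
  )
}

#' Build a read-similarity graph from pooled reads
#'
#' Candidate read pairs are found by shared-k-mer indexing (a pair is
#' considered iff the two reads share at least `min_shared_kmers`
#' distinct k-mers), so no all-vs-all alignment is attempted. Each
#' candidate pair is then scored by an ungapped overlap alignment scanned
#' over every shift whose overlap covers at least `min_coverage` of the
#' read length; an edge is created iff the best such overlap reaches
#' `min_identity`, with weight identity x coverage. The thresholds mirror
#' the conventional 90% identity over at least 55% of the read length
#' used for read-based repeat clustering.
#'
#' Comparison is strand-aware (forward vs forward), matching reads
#' simulated from a single strand; see the package vignette.
#'
#' @param pooled a pooled, uniform-length read_set (see [pool_reads()])
#' @param k seed k-mer length (default 17)
#' @param min_identity minimum overlap identity for an edge (default 0.90)
#' @param min_coverage minimum overlap fraction of read length (default 0.55)
#' @param min_shared_kmers distinct shared k-mers required for a
#'   candidate pair (default 2)
#' @return an object of class `read_graph`: vertex ids (sorted), an edge
#'   table with weights, and the read length
#' @export
build_similarity_graph <- function(pooled, k = 17L, min_identity = 0.90,
                                   min_coverage = 0.55, min_shared_kmers = 2L) {
  stopifnot(inherits(pooled, "read_set"))
  if (length(pooled) < 2L) stop("need at least two reads to build a graph")
  L <- read_length(pooled)  # errors if not uniform
  if (k > L) stop("k-mer length exceeds read length")

  ord <- order(pooled$read_id, method = "radix")
  ids <- pooled$read_id[ord]
  seqs <- pooled$sequence[ord]

  km <- extract_kmers(seqs, k)
  # self-join on k-mer -> candidate pairs with shared-k-mer counts
  pairs <- km[km, on = "kmer", allow.cartesian = TRUE][read < i.read]
  edges <- data.frame(from = character(0), to = character(0),
                      weight = numeric(0), identity = numeric(0),
                      coverage = numeric(0), shift = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    shared <- unique(pairs, by = c("read", "i.read", "kmer"))[
      , .N, by = .(a = read, b = i.read)][N >= min_shared_kmers]
    if (nrow(shared)) {
      sc <- scan_candidate_pairs(seqs, shared$a, shared$b,
                                 min_identity, min_coverage)
      keep <- which(sc$keep)
      edges <- data.frame(
        from = ids[shared$a[keep]], to = ids[shared$b[keep]],
        weight = sc$weight[keep], identity = sc$identity[keep],
        coverage = sc$coverage[keep], shift = sc$shift[keep],
        stringsAsFactors = FALSE
      )
    }
  }
  stopifnot(all(edges$weight > 0), all(edges$weight <= 1),
            all(edges$from != edges$to))
  structure(
    list(read_ids = ids, edges = edges, read_length = L,
         params = list(k = k, min_identity = min_identity,
                       min_coverage = min_coverage,
                       min_shared_kmers = min_shared_kmers)),
    class = "read_graph"
  )
}

#' @export
print.read_graph <- function(x, ...) {
  cat(sprintf("read_graph: %d reads, %d edges (read length %d)\n",
              length(x$read_ids), nrow(x$edges), x$read_length))
  invisible(x)
}

#' Partition a read graph into repeat clusters
#'
#' Connected components are computed first; components larger than
#' `min_split_size` vertices are further split by greedy modularity
#' maximization (weighted fast-greedy agglomeration at resolution 1).
#' Because reads overlap only when their positions within a repeat unit
#' are close, a single family's subgraph is chain-like along the unit
#' coordinate, and raw modularity optimization happily cuts such chains
#' into positional segments. A split is therefore kept only where the
#' cut is weak: communities still connected by at least
#' `merge_min_edges` edges are merged back (the counterpart of the
#' cluster-merging step in read-clustering pipelines). A genuine
#' continuation of one repeat unit yields an overlap band of tens of
#' edges across any positional cut, while distinct families lumped by
#' chance share only isolated edges, so the two cases separate cleanly
#' on an absolute count.
#'
#' Vertices without any edge are excluded from clusters. With the
#' package's lexicographic vertex ordering the procedure is
#' deterministic; `seed` is accepted for interface stability but the
#' current algorithm draws no random numbers.
#'
#' @param g a read_graph
#' @param seed integer seed (unused by the deterministic algorithm)
#' @param min_split_size only components above this size are candidates
#'   for modularity splitting (default 100)
#' @param merge_min_edges communities connected by at least this many
#'   edges are re-merged after splitting (default 10)
#' @return list of character vectors of member read ids, each sorted
#' @export
partition_graph <- function(g, seed = 1L, min_split_size = 100L,
                            merge_min_edges = 10L) {
  stopifnot(inherits(g, "read_graph"))
  if (nrow(g$edges) == 0L) return(list())
  used <- sort(unique(c(g$edges$from, g$edges$to)))
  gr <- igraph::graph_from_data_frame(
    g$edges[c("from", "to", "weight")], directed = FALSE,
    vertices = data.frame(name = used, stringsAsFactors = FALSE))
  comp <- igraph::components(gr)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- used[comp$membership == ci]
    if (length(members) > min_split_size) {
      sub <- igraph::induced_subgraph(gr, members)
      cm <- igraph::cluster_fast_greedy(sub,
                                        weights = igraph::E(sub)$weight)
      memb <- merge_weak_splits(sub, as.integer(igraph::membership(cm)),
                                merge_min_edges)
      grp <- split(igraph::V(sub)$name, memb)
      out <- c(out, unname(grp))
    } else {
      out <- c(out, list(members))
    }
  }
  lapply(out, sort)
}

# undo modularity splits whose cut is strong: while any community pair
# is connected by >= merge_min_edges edges, merge the most strongly
# connected pair
merge_weak_splits <- function(sub, memb, merge_min_edges) {
  el <- igraph::as_edgelist(sub, names = FALSE)
  repeat {
    ka <- memb[el[, 1]]
    kb <- memb[el[, 2]]
    between <- ka != kb
    if (!any(between)) return(memb)
    cnt <- sort(table(paste(pmin(ka[between], kb[between]),
                            pmax(ka[between], kb[between]))),
                decreasing = TRUE)
    if (cnt[[1]] < merge_min_edges) return(memb)
    ab <- as.integer(strsplit(names(cnt)[1], " ")[[1]])
    memb[memb == ab[2]] <- ab[1]
  }
}

#' Construct a cluster-by-species count table
#'
#' The central exchange format of the pipeline: one row per repeat
#' cluster, one count column per species, rows ordered by total size
#' descending (ties by cluster_id). Extra columns (e.g. a `family_id`
#' truth column from simulation) are carried through.
#'
#' @param df data.frame containing one numeric column per species code
#' @param species_codes character vector of five-letter codes
#' @param members optional named list: cluster_id -> member read ids
#' @return an object of classes `cluster_table` and `data.frame`
#' @export
as_cluster_table <- function(df, species_codes, members = NULL) {
  for (code in species_codes) validate_species_code(code)
  stopifnot(all(species_codes %in% names(df)))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  cnt <- as.matrix(df[species_codes])
  stopifnot(all(cnt >= 0))
  df$total <- rowSums(cnt)
  if (is.null(df$cluster_id)) {
    tie <- if (!is.null(df$family_id)) df$family_id else seq_len(nrow(df))
    ord <- order(-df$total, tie)
    df <- df[ord, , drop = FALSE]
    df$cluster_id <- if (nrow(df)) sprintf("CL%d", seq_len(nrow(df))) else character(0)
  } else {
    df <- df[order(-df$total, df$cluster_id), , drop = FALSE]
  }
  if (is.null(df$contaminant)) df$contaminant <- FALSE
  rownames(df) <- NULL
  front <- c("cluster_id", species_codes, "total", "contaminant")
  df <- df[c(front, setdiff(names(df), front))]
  structure(df, species_codes = species_codes, members = members,
            class = c("cluster_table", "data.frame"))
}

#' Member read ids of the clusters in a cluster table
#' @param table a cluster_table built by [tabulate_clusters()]
#' @return named list: cluster_id -> character vector of read ids
#' @export
cluster_members <- function(table) attr(table, "members")

#' Tabulate a graph partition into a cluster-by-species count table
#'
#' Attributes every clustered read to its species through the five-letter
#' identifier prefix and names clusters CL1, CL2, ... by total size
#' descending (ties broken by the lexicographically smallest member read
#' id, so the ranking is deterministic).
#'
#' @param partition list of member read-id vectors from [partition_graph()]
#' @param species_codes the species codes present in the pool
#' @return a [as_cluster_table()] with membership attached
#' @export
tabulate_clusters <- function(partition, species_codes) {
  for (code in species_codes) validate_species_code(code)
  if (length(partition) == 0L)
    return(as_cluster_table(
      stats::setNames(as.data.frame(matrix(numeric(0), 0, length(species_codes))),
                      species_codes),
      species_codes, members = list()))
  all_ids <- unlist(partition, use.names = FALSE)
  pref <- species_prefix(all_ids)
  bad <- which(!(pref %in% species_codes))
  if (length(bad))
    stop("read id without a recognized species prefix: ", all_ids[bad[1]])

  grp <- rep.int(seq_along(partition), lengths(partition))
  cnt <- table(factor(grp, levels = seq_along(partition)),
               factor(pref, levels = species_codes))
  df <- as.data.frame.matrix(cnt)
  names(df) <- species_codes
  total <- rowSums(df)
  first_id <- vapply(partition, `[`, character(1), 1L)
  ord <- order(-total, first_id, method = "radix")
  df <- df[ord, , drop = FALSE]
  df$cluster_id <- sprintf("CL%d", seq_len(nrow(df)))
  members <- stats::setNames(partition[ord], df$cluster_id)
  as_cluster_table(df, species_codes, members = members)
}
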