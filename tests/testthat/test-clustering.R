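test_that("identical reads connect at weight 1; k-mer-disjoint reads do not connect", {
  s <- with_seed(1, random_dna(1, 91))
  twin <- mk_reads(c(s, s), ids = c("AAAAA_r1", "AAAAA_r2"))
  g <- build_similarity_graph(twin)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1)
  expect_equal(g$edges$shift, 0L)

  pair <- mk_reads(with_seed(2, random_dna(2, 91)),
                   ids = c("AAAAA_r1", "AAAAA_r2"))
  g2 <- build_similarity_graph(pair)
  expect_equal(nrow(g2$edges), 0)

  # contract violations
  expect_error(build_similarity_graph(mk_reads(s)), "at least two")
  ragged <- read_set(c("a", "b"), c(strrep("A", 91), strrep("A", 80)),
                     c(strrep("D", 91), strrep("D", 80)))
  expect_error(build_similarity_graph(ragged), "uniform")
})

test_that("edge rule matches a brute-force all-pairs enumeration oracle", {
  g <- planted_genome()
  rs <- generate_reads(g, 0.02, 91, error_rate = 0, seed = 42)
  keep <- with_seed(9, sort(sample(seq_along(rs$read_id), 400)))
  sub <- tag_species(rs[keep], "AAAAA")
  orc <- oracle_edges(sub$sequence)
  orc_ids <- sub$read_id  # order of sequences fed to the oracle

  gr <- build_similarity_graph(sub)
  imp <- graph_edge_keys(gr, orc_ids)
  expect_identical(nrow(imp), nrow(orc))
  key_o <- paste(orc$a, orc$b)
  key_i <- paste(imp$a, imp$b)
  expect_setequal(key_i, key_o)
  merged <- merge(data.frame(key = key_o, wo = orc$w),
                  data.frame(key = key_i, wi = imp$w))
  expect_equal(merged$wo, merged$wi, tolerance = 1e-12)

  # no edges leak across families or into random background
  fam <- stats::setNames(sub$family, sub$read_id)
  expect_true(all(fam[gr$edges$from] == fam[gr$edges$to]))
  expect_false(any(fam[gr$edges$from] == "single_copy"))
})

mk_graph <- function(edges_df, ids) {
  structure(list(read_ids = sort(ids), edges = edges_df, read_length = 91L,
                 params = list()), class = "read_graph")
}

clique_edges <- function(ids, weight = 1) {
  idx <- t(utils::combn(ids, 2))
  data.frame(from = idx[, 1], to = idx[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

test_that("weakly joined communities split as the exhaustive modularity optimum", {
  a <- sprintf("AAAAA_a%02d", 1:8)
  b <- sprintf("AAAAA_b%02d", 1:8)
  edges <- rbind(clique_edges(a), clique_edges(b),
                 data.frame(from = a[1], to = b[1], weight = 1))
  g <- mk_graph(edges, c(a, b))
  part <- partition_graph(g, min_split_size = 10)
  expect_length(part, 2)
  expect_setequal(unlist(part), c(a, b))
  expect_identical(adjusted_rand_index(
    partition_membership(part)[c(a, b)],
    rep(1:2, each = 8)), 1)

  # exhaustive bipartition oracle: the returned split maximizes modularity
  ig <- igraph::graph_from_data_frame(edges, directed = FALSE)
  nodes <- igraph::V(ig)$name
  best_q <- -Inf; best_side <- NULL
  for (mask in 0:(2^15 - 1)) {  # node 16 fixed to side 0
    side <- c(as.integer(intToBits(mask))[1:15], 0L)
    if (all(side == 0L)) next
    q <- igraph::modularity(ig, side + 1L)
    if (q > best_q) { best_q <- q; best_side <- side }
  }
  memb <- partition_membership(part)
  expect_equal(adjusted_rand_index(memb[nodes], best_side), 1)
  # and the achieved modularity equals the exhaustive optimum
  expect_equal(igraph::modularity(ig, memb[nodes]), best_q)
})

test_that("strongly connected communities are re-merged; disjoint cliques stay apart", {
  a <- sprintf("AAAAA_a%02d", 1:12)
  b <- sprintf("AAAAA_b%02d", 1:12)
  bridge <- data.frame(from = rep(a[1:4], each = 3), to = rep(b[1:3], 4),
                       weight = 1)
  g <- mk_graph(rbind(clique_edges(a), clique_edges(b), bridge), c(a, b))
  part <- partition_graph(g, min_split_size = 10)
  expect_length(part, 1)  # 12 connecting edges >= merge_min_edges

  g2 <- mk_graph(rbind(clique_edges(a), clique_edges(b)), c(a, b))
  part2 <- partition_graph(g2, min_split_size = 10)
  expect_length(part2, 2)
  part3 <- partition_graph(mk_graph(clique_edges(a), a), min_split_size = 100)
  expect_length(part3, 1)
})

test_that("partitions are disjoint and cover every vertex with an edge", {
  g <- planted_genome(n_fam = 6)
  rs <- tag_species(generate_reads(g, 0.01, 91, error_rate = 0.01, seed = 8),
                    "AAAAA")
  gr <- build_similarity_graph(rs)
  part <- partition_graph(gr)
  ids <- unlist(part)
  expect_identical(anyDuplicated(ids), 0L)
  expect_setequal(ids, unique(c(gr$edges$from, gr$edges$to)))
  # graph is symmetric by construction: each unordered pair appears once
  keys <- paste(pmin(gr$edges$from, gr$edges$to),
                pmax(gr$edges$from, gr$edges$to))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("planted families are recovered as single clusters (ARI >= 0.9)", {
  g <- planted_genome()
  rs <- tag_species(generate_reads(g, 0.02, 91, error_rate = 0, seed = 42),
                    "AAAAA")
  gr <- build_similarity_graph(rs)
  part <- partition_graph(gr)
  memb <- partition_membership(part)
  fam <- stats::setNames(rs$family, rs$read_id)
  ids <- names(memb)
  expect_gte(adjusted_rand_index(fam[ids], memb[ids]), 0.9)
  # >= 90% of each family's reads land in one cluster
  for (f in unique(fam[fam != "single_copy"])) {
    members <- memb[names(fam)[fam == f]]
    members <- members[!is.na(members)]
    frac <- max(table(members)) / sum(fam == f)
    expect_gte(frac, 0.9)
  }
})

test_that("cluster tabulation counts species prefixes and conserves reads", {
  part <- list(c("AAAAA_1", "AAAAA_2", "BBBBB_1"),
               c("BBBBB_2", "CCCCC_9"),
               c("CCCCC_1", "CCCCC_2", "CCCCC_3", "AAAAA_9"))
  tab <- tabulate_clusters(part, c("AAAAA", "BBBBB", "CCCCC"))
  expect_identical(tab$cluster_id, c("CL1", "CL2", "CL3"))
  # largest first; the 3-read and 4-read clusters rank by size
  expect_equal(tab$total, c(4, 3, 2))
  expect_equal(unlist(tab[tab$total == 3, c("AAAAA", "BBBBB", "CCCCC")],
                      use.names = FALSE), c(2, 1, 0))
  expect_equal(sum(tab$total), length(unlist(part)))
  expect_identical(cluster_members(tab)$CL2, part[[1]])

  expect_error(tabulate_clusters(list(c("ZZZZZ_1")), c("AAAAA", "BBBBB")),
               "ZZZZZ_1")
})

test_that("partition agreement scoring matches the pair-counting formula", {
  for (seed in 1:10) {
    labs <- with_seed(seed, list(a = sample(letters[1:4], 60, replace = TRUE),
                                 b = sample(1:5, 60, replace = TRUE)))
    expect_equal(adjusted_rand_index(labs$a, labs$b),
                 ari_formula(labs$a, labs$b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
})

test_that("per-species counts scale linearly with the sampling proportion", {
  g <- suppressMessages(calibration_genomes(12, seed = 5))
  t1 <- simulate_cluster_table(g$maternal, g$paternal, g$tetraploid,
                               proportion = 0.01, seed = 21)
  t2 <- simulate_cluster_table(g$maternal, g$paternal, g$tetraploid,
                               proportion = 0.02, seed = 22)
  c1 <- t1$MATER[match(t2$family_id, t1$family_id)]
  big <- t2$MATER >= 50
  ratio <- t2$MATER[big] / c1[big]
  # doubling the proportion doubles counts within binomial error
  expect_true(all(abs(ratio - 2) < 2 * 2 / sqrt(c1[big])))
})
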