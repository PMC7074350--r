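test_that("worked filtering examples behave as documented", {
  #               m    p    t
  tab <- mk_table(c( 50,  12,  15, 100,  30),
                  c(  0,  15,   0,  80,   0),
                  c(  0,   9,  20, 150,   5))
  out <- apply_filters(tab, std_design())
  log <- filter_log(out)
  reason_of <- function(m, p, t) {
    id <- tab$cluster_id[tab$MATER == m & tab$PATER == p & tab$TETRA == t]
    log$reason[log$cluster_id == id]
  }
  # parents-only / single-species clusters
  expect_identical(reason_of(50, 0, 0), "species_specific")
  expect_identical(reason_of(30, 0, 5), "species_specific")
  # present in both parents but below 10 reads in the tetraploid
  expect_identical(reason_of(12, 15, 9), "absent_in_tetraploid")
  # retained: tetraploid + one parent -> usable for that regression only
  kept <- as.data.frame(out)
  expect_identical(kept$usable[kept$MATER == 15], "maternal_only")
  expect_identical(kept$usable[kept$MATER == 100], "both")
  expect_identical(nrow(kept), 2L)
})

test_that("filtering is monotone in min_reads and reasons partition removals", {
  for (seed in 1:20) {
    cnt <- with_seed(seed, matrix(rpois(60, 12), ncol = 3))
    tab <- mk_table(cnt[, 1], cnt[, 2], cnt[, 3])
    prev <- NULL
    for (mr in c(5, 10, 15, 20)) {
      out <- apply_filters(tab, std_design(), min_reads = mr)
      if (!is.null(prev)) expect_true(all(out$cluster_id %in% prev))
      prev <- out$cluster_id
      log <- filter_log(out)
      expect_identical(anyDuplicated(log$cluster_id), 0L)
      expect_false(any(is.na(log$reason)))
      expect_setequal(c(out$cluster_id, log$cluster_id), tab$cluster_id)
    }
  }
})

test_that("strict all-species rule and parents-only retention are available", {
  tab <- mk_table(c(100, 15, 12), c(80, 0, 15), c(150, 20, 0))
  strict <- apply_filters(tab, std_design(), require_all_species = TRUE)
  expect_identical(nrow(strict), 1L)
  expect_setequal(filter_log(strict)$reason,
                  c("absent_in_some_species", "absent_in_some_species"))

  keep <- apply_filters(tab, std_design(), keep_parents_only = TRUE)
  kept <- as.data.frame(keep)
  expect_identical(kept$usable[kept$TETRA == 0], "deviation_only")
  # default drops the parents-only cluster
  dropped <- apply_filters(tab, std_design())
  expect_true("absent_in_tetraploid" %in% filter_log(dropped)$reason)
})

test_that("contaminant flagging counts k-mer matches against references", {
  chloro <- with_seed(33, random_dna(1, 2000))
  clean <- with_seed(34, random_dna(12, 91))
  starts <- seq(1, 1800, length.out = 12)
  dirty <- substring(chloro, starts, starts + 90)
  # cluster CLa: all contaminant; CLb: 40% contaminant; CLc: clean
  seqs <- c(dirty[1:5], dirty[6:7], clean[1:3], clean[4:12])
  ids <- c(sprintf("AAAAA_c%d", 1:5), sprintf("AAAAA_m%d", 1:5),
           sprintf("AAAAA_x%d", 1:9))
  rs <- mk_reads(seqs, ids = ids)
  part <- list(ids[1:5], ids[6:10], ids[11:19])
  tab <- tabulate_clusters(part, "AAAAA")

  out <- flag_contaminants(tab, rs, chloro, min_fraction = 0.5)
  expect_setequal(out$contaminant[out$total == 5], c(TRUE, FALSE))
  expect_false(out$contaminant[out$total == 9])
  expect_equal(out$contaminant_fraction[out$contaminant], 1)
  # mixed cluster: brute-force k-mer membership count says 2 of 5 reads
  ref_km <- unique(substring(chloro, 1:(2000 - 16), 17:2000))
  ref_can <- unique(pmin(ref_km, polyrep:::reverse_complement_chr(ref_km)))
  hits <- vapply(seqs[6:10], function(s) {
    km <- substring(s, 1:75, 17:91)
    any(pmin(km, polyrep:::reverse_complement_chr(km)) %in% ref_can)
  }, logical(1))
  expect_equal(sum(hits), 2)
  mixed <- out[out$total == 5 & !out$contaminant, ]
  expect_equal(mixed$contaminant_fraction, 0.4)

  # reverse-complement reads still match (canonical k-mers)
  rc <- mk_reads(polyrep:::reverse_complement_chr(dirty[1:3]),
                 ids = sprintf("AAAAA_r%d", 1:3))
  tab_rc <- tabulate_clusters(list(rc$read_id), "AAAAA")
  expect_true(flag_contaminants(tab_rc, rc, chloro)$contaminant)

  # empty reference set flags nothing
  none <- flag_contaminants(tab, rs, character(0))
  expect_false(any(none$contaminant))

  # flagged clusters are removed with the contaminant reason
  d3 <- cross_design("AAAAA", "BBBBB", "CCCCC")
  tab3 <- mk_table(c(20, 20), c(20, 20), c(20, 20),
                   codes = c("AAAAA", "BBBBB", "CCCCC"))
  tab3$contaminant <- c(TRUE, FALSE)
  filt <- apply_filters(tab3, d3)
  expect_identical(filter_log(filt)$reason, "contaminant")
  expect_identical(nrow(filt), 1L)
})

test_that("abundant families survive filtering on additive synthetic data", {
  survived <- vapply(1:10, function(seed) {
    g <- suppressMessages(calibration_genomes(40, seed = seed))
    tab <- simulate_cluster_table(g$maternal, g$paternal, g$tetraploid,
                                  seed = 1000 + seed)
    # families whose expected read count is >= 2 x min_reads in all species
    exp_counts <- vapply(g, function(gen) {
      n <- reads_for_proportion(gen$c_value_bp)
      ab <- family_abundance(gen)
      n * ab[tab$family_id] * 500 / gen$c_value_bp
    }, numeric(nrow(tab)))
    eligible <- tab$family_id[apply(exp_counts >= 20, 1, all)]
    out <- apply_filters(tab, std_design(), min_reads = 10)
    mean(eligible %in% out$family_id)
  }, numeric(1))
  expect_gte(mean(survived), 0.95)
})
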