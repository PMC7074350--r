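test_that("zero divergence with shared perturbation seed gives identical parents", {
  pair <- simulate_parents(n_families = 8, abundance_exponent = 1.8,
                           divergence = 0, c_value_bp = 1e6, seed = 3,
                           maternal_seed = 101, paternal_seed = 101)
  expect_identical(family_abundance(pair$maternal),
                   family_abundance(pair$paternal))
  expect_identical(pair$maternal$families$consensus,
                   pair$paternal$families$consensus)
})

test_that("n_families = 0 yields background-only genomes that still emit reads", {
  pair <- simulate_parents(0, 1.5, 0.1, 5e5, seed = 1)
  expect_identical(nrow(pair$maternal$families), 0L)
  rs <- generate_reads(pair$maternal, proportion = 0.02, read_length = 91,
                       error_rate = 0, seed = 2)
  expect_true(all(rs$family == "single_copy"))
  expect_equal(length(rs), round(0.02 * 5e5 / 91))
})

test_that("repeat content never exceeds the 1C size (direct summation oracle)", {
  for (seed in 1:10) {
    pair <- simulate_parents(20, 1.3, 0.05, 2e6, seed = seed,
                             min_copies = 50, max_copies = 4000)
    for (g in pair) {
      expect_lte(sum(g$families$copies_per_1C * g$families$unit_length),
                 g$c_value_bp)
    }
  }
  # forcing an overflow triggers proportional rescaling, with a message
  expect_message(
    simulate_parents(10, 1.2, 0, 1e6, seed = 5, min_copies = 500,
                     max_copies = 2000),
    "rescaled")
})

make_parents_fixed <- function(m_copies, p_copies, unit = 100L, seed = 7) {
  n <- length(m_copies)
  cons <- with_seed(seed, random_dna(n, unit))
  fam <- sprintf("FAM%02d", seq_len(n))
  mk <- function(copies, code) {
    genome_spec(code, 1e7,
                data.frame(family_id = fam, consensus = cons,
                           copies_per_1C = copies,
                           per_copy_divergence = 0.01),
                single_copy_fraction = 0.3)
  }
  list(maternal = mk(m_copies, "MATER"), paternal = mk(p_copies, "PATER"))
}

test_that("inheritance modes reproduce per-family hand computation", {
  par <- make_parents_fixed(c(100, 800, 40, 1200, 0),
                            c(50, 900, 0, 150, 60))
  add <- apply_inheritance(par$maternal, par$paternal,
                           inheritance_model("additive"))
  expect_equal(unname(family_abundance(add)),
               c(150, 1700, 40, 1350, 60))

  bias <- apply_inheritance(par$maternal, par$paternal,
                            inheritance_model("parent_bias", bias_rho = 0.5))
  expect_equal(unname(family_abundance(bias)),
               c(100 + 25, 800 + 450, 40, 1200 + 75, 30))

  bias_m <- apply_inheritance(
    par$maternal, par$paternal,
    inheritance_model("parent_bias", bias_rho = 2, biased_parent = "maternal"))
  expect_equal(unname(family_abundance(bias_m)),
               c(250, 2500, 80, 2550, 60))

  # size-dependent: brute-force application of the rule, family by family
  model <- inheritance_model("size_dependent", size_threshold = 1000,
                             size_factor = 2)
  sd_tet <- apply_inheritance(par$maternal, par$paternal, model)
  m <- c(100, 800, 40, 1200, 0); p <- c(50, 900, 0, 150, 60)
  expected <- vapply(seq_along(m), function(i) {
    s <- m[i] + p[i]
    if (s >= 1000) floor(abs(2 * s) + 0.5) * sign(s) else s
  }, numeric(1))
  expect_equal(unname(family_abundance(sd_tet)), expected)
  # tetraploid 1C is single-copy content plus inherited repeat content
  expect_equal(sd_tet$c_value_bp,
               0.3 * 1e7 * 2 + sum(expected * 100))
})

test_that("mismatched unit lengths for a shared family id are rejected", {
  par <- make_parents_fixed(c(100, 50), c(60, 70))
  par$paternal$families$consensus[1] <-
    substr(par$paternal$families$consensus[1], 1, 50)
  par$paternal$families$unit_length[1] <- 50L
  expect_error(apply_inheritance(par$maternal, par$paternal,
                                 inheritance_model("additive")),
               "unit_length mismatch")
})

test_that("read count follows the genome-proportion formula and FASTQ round-trips", {
  g <- planted_genome(n_fam = 4, copies = 400, c_value = 1e6,
                      per_copy_divergence = 0)
  rs <- generate_reads(g, proportion = 0.02, read_length = 91,
                       error_rate = 0.01, seed = 5)
  expect_equal(length(rs), 220)  # round(0.02 * 1e6 / 91) = round(219.78)
  expect_equal(reads_for_proportion(1e6, 0.02, 91), 220)

  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(rs, f1)
  back <- read_fastq(f1)
  expect_identical(back$sequence, rs$sequence)
  expect_identical(back$read_id, rs$read_id)
  # fixed seed => byte-identical FASTQ on rerun
  write_fastq(generate_reads(g, 0.02, 91, error_rate = 0.01, seed = 5), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  expect_error(generate_reads(g, proportion = 1e-5, read_length = 91,
                              error_rate = 0, seed = 1),
               "below one read")
})

test_that("noise-free reads are exact substrings of their family consensus", {
  g <- planted_genome(n_fam = 3, copies = 500, c_value = 1e6,
                      per_copy_divergence = 0, seed = 4)
  rs <- generate_reads(g, 0.02, 91, error_rate = 0, seed = 9)
  fam_reads <- rs$family != "single_copy"
  cons <- stats::setNames(g$families$consensus, g$families$family_id)
  hits <- vapply(which(fam_reads), function(i) {
    grepl(rs$sequence[i], cons[[rs$family[i]]], fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
})

test_that("per-family read counts are multinomial around bp proportions", {
  # chi-square goodness of fit at ~11k reads should rarely reject
  g <- suppressMessages(calibration_genomes(20, seed = 2,
                                            c_value_bp = 5e7)$maternal)
  probs <- polyrep:::source_probs(g)
  lab <- c(g$families$family_id, "single_copy")
  rejections <- vapply(1:100, function(s) {
    rs <- generate_reads(g, 0.02, 91, error_rate = 0, seed = 1000 + s)
    obs <- table(factor(rs$family, levels = lab))
    suppressWarnings(stats::chisq.test(obs, p = probs)$p.value) < 0.01
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})

test_that("additive tetraploid abundance equals the parental sum for any seed", {
  for (seed in c(2, 17, 303)) {
    g <- suppressMessages(calibration_genomes(25, seed = seed))
    expect_identical(
      family_abundance(g$tetraploid),
      family_abundance(g$maternal) + family_abundance(g$paternal))
  }
})
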