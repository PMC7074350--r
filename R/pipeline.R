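#' Assemble and validate a pipeline configuration
#'
#' A run is driven either by a simulation scenario (the packaged default)
#' or by three FASTQ files. All stage parameters default to the values
#' used throughout the package: 91 bp reads at a 2% genome proportion,
#' Phred > 10 with at most 3 Ns, presence threshold of 10 reads per
#' species.
#'
#' @param scenario NULL, or a list describing the simulation:
#'   n_families, abundance_exponent, divergence, c_value_bp,
#'   inheritance (an [inheritance_model()]), error_rate, and optionally
#'   per_copy_divergence, single_copy_fraction, unit_length, perturb_sd
#' @param fastq NULL, or named list with elements maternal, paternal,
#'   tetraploid giving FASTQ paths
#' @param c_values named numeric (maternal, paternal, tetraploid) 1C
#'   sizes in bp; required in FASTQ mode, derived from the simulated
#'   genomes in scenario mode
#' @param codes named character vector of five-letter codes for roles
#'   maternal, paternal, tetraploid
#' @param proportion genome proportion for subsampling (default 0.02)
#' @param read_length uniform read length after trimming (default 91)
#' @param min_phred,max_n quality-filter parameters (defaults 10, 3)
#' @param cluster list of clustering parameters: k, min_identity,
#'   min_coverage, min_shared_kmers, min_split_size
#' @param filters list: min_reads, require_all_species,
#'   keep_parents_only, contaminants (FASTA path or NULL),
#'   contaminant_min_fraction
#' @param seed global integer seed; per-stage seeds derive from it
#' @return validated config object of class `pipeline_config`
#' @export
pipeline_config <- function(scenario = NULL, fastq = NULL, c_values = NULL,
                            codes = c(maternal = "MATER", paternal = "PATER",
                                      tetraploid = "TETRA"),
                            proportion = 0.02, read_length = 91L,
                            min_phred = 10L, max_n = 3L,
                            cluster = list(), filters = list(), seed = 1L) {
  roles <- c("maternal", "paternal", "tetraploid")
  if (!all(roles %in% names(codes)))
    stop("codes must name all roles: ", paste(roles, collapse = ", "))
  extra <- setdiff(names(codes), roles)
  if (length(extra)) stop("unknown species role in codes: ",
                          paste(extra, collapse = ", "))
  for (code in codes) validate_species_code(code)
  if (anyDuplicated(codes)) stop("species codes must be distinct")
  if (is.null(scenario) == is.null(fastq))
    stop("exactly one of scenario or fastq must be given")
  if (!is.null(fastq)) {
    if (!all(roles %in% names(fastq)))
      stop("fastq must name all roles: ", paste(roles, collapse = ", "))
    if (is.null(c_values) || !all(roles %in% names(c_values)))
      stop("c_values must be provided per role in FASTQ mode")
  }
  if (!is.null(scenario)) {
    need <- c("n_families", "abundance_exponent", "divergence", "c_value_bp",
              "inheritance")
    miss <- setdiff(need, names(scenario))
    if (length(miss)) stop("scenario is missing: ", paste(miss, collapse = ", "))
    if (!inherits(scenario$inheritance, "inheritance_model"))
      stop("scenario$inheritance must be an inheritance_model")
  }
  cl <- utils::modifyList(
    list(k = 17L, min_identity = 0.90, min_coverage = 0.55,
         min_shared_kmers = 2L, min_split_size = 100L), cluster)
  fl <- utils::modifyList(
    list(min_reads = 10L, require_all_species = FALSE,
         keep_parents_only = FALSE, contaminants = NULL,
         contaminant_min_fraction = 0.5), filters)
  stopifnot(proportion > 0, proportion <= 1,
            cl$min_identity > 0, cl$min_identity <= 1,
            cl$min_coverage > 0, cl$min_coverage <= 1,
            fl$min_reads >= 0)
  structure(list(scenario = scenario, fastq = fastq, c_values = c_values,
                 codes = codes, proportion = proportion,
                 read_length = as.integer(read_length),
                 min_phred = min_phred, max_n = max_n,
                 cluster = cl, filters = fl, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' A small packaged demonstration scenario
#'
#' Twelve shared repeat families in 2 Mbp parental genomes with an
#' additive tetraploid by default — sized so the whole pipeline,
#' including sequence-level clustering, runs in seconds. The copy-number
#' floor keeps every family abundant enough to be sampled as a dense,
#' recoverable cluster at the 2% genome proportion (the drawn repeat
#' content typically saturates the 70% repeat budget, which is realistic
#' for repeat-rich plant genomes).
#'
#' @param inheritance an [inheritance_model()] (default additive)
#' @param n_families,c_value_bp scenario size knobs
#' @return a scenario list for [pipeline_config()]
#' @export
demo_scenario <- function(inheritance = inheritance_model("additive"),
                          n_families = 12L, c_value_bp = 2e6) {
  list(n_families = n_families, abundance_exponent = 1.6,
       divergence = 0.10, c_value_bp = c_value_bp,
       per_copy_divergence = 0.02, single_copy_fraction = 0.3,
       error_rate = 0.005, min_copies = 150, max_copies = 3000,
       inheritance = inheritance)
}

#' Genome trio for statistical calibration experiments
#'
#' Builds maternal, paternal and tetraploid genomes in the
#' abundant-family regime: every family's copy number is drawn from a
#' bounded power law with a floor high enough that, at the 2% genome
#' proportion, each family yields comfortably more than the presence
#' threshold of reads in every species. Used with
#' [simulate_cluster_table()] for type-I-error and power experiments on
#' the slope-equality test, where the object of study is count noise
#' and parental perturbation, not sequence-level clustering.
#'
#' @param n_families number of repeat families (the cluster count)
#' @param inheritance an [inheritance_model()]
#' @param seed integer seed
#' @param c_value_bp parental 1C size in bp
#' @param perturb_sd between-parent lognormal abundance divergence: 0.25
#'   (default) is the count-noise-dominated regime; 1.0 emulates
#'   strongly diverged diploid progenitors whose family abundances
#'   differ by multiples
#' @param min_copies,max_copies copy-number power-law support
#' @return list with maternal, paternal, tetraploid genome_spec
#' @export
calibration_genomes <- function(n_families = 100L,
                                inheritance = inheritance_model("additive"),
                                seed = 1L, c_value_bp = NULL,
                                perturb_sd = 0.25,
                                min_copies = 150, max_copies = 3000) {
  # c scales with family count so the repeat fraction stays ~0.6
  c_value_bp <- c_value_bp %||% (n_families * 5e5)
  parents <- simulate_parents(
    n_families = n_families, abundance_exponent = 1.6, divergence = 0,
    c_value_bp = c_value_bp, seed = seed, unit_length = 500L,
    min_copies = min_copies, max_copies = max_copies,
    perturb_sd = perturb_sd)
  tet <- apply_inheritance(parents$maternal, parents$paternal, inheritance)
  list(maternal = parents$maternal, paternal = parents$paternal,
       tetraploid = tet)
}

#' Repeated slope-equality experiment on simulated cluster tables
#'
#' Runs the count-level pipeline (calibration genomes, multinomial
#' cluster table, presence filtering, deviation records, stacked
#' slope-equality F-test) `n_reps` times and collects p-values — the
#' engine behind the type-I-error and power experiments.
#'
#' @param n_families families per dataset
#' @param inheritance an [inheritance_model()] (additive gives the null)
#' @param n_reps number of simulated datasets
#' @param seed integer seed; per-repetition sub-seeds derive from it
#' @param perturb_sd between-parent abundance divergence (see
#'   [calibration_genomes()])
#' @param alpha rejection level (default 0.05)
#' @return list: p_values, n_clusters (usable per repetition),
#'   rejection_rate
#' @export
slope_test_experiment <- function(n_families, inheritance, n_reps, seed,
                                  perturb_sd = 0.25, alpha = 0.05) {
  design <- cross_design("MATER", "PATER", "TETRA")
  seeds <- with_seed(seed,
                     matrix(sample.int(.Machine$integer.max - 1L, 2L * n_reps),
                            ncol = 2))
  p_values <- numeric(n_reps)
  n_clusters <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    g <- suppressMessages(calibration_genomes(
      n_families, inheritance, seed = seeds[i, 1], perturb_sd = perturb_sd))
    tab <- simulate_cluster_table(g$maternal, g$paternal, g$tetraploid,
                                  seed = seeds[i, 2])
    st <- slope_equality_test(
      deviation_table(apply_filters(tab, design), design), design)
    p_values[i] <- st$p_value
    n_clusters[i] <- st$n_clusters
  }
  list(p_values = p_values, n_clusters = n_clusters,
       rejection_rate = mean(p_values < alpha))
}

# documented seed-splitting rule: the global seed seeds one RNG draw of
# six sub-seeds, consumed in stage order
stage_seeds <- function(seed) {
  s <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 6L))
  stats::setNames(s, c("simulate", "reads", "subsample", "cluster",
                       "unused1", "unused2"))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full comparative repeat-abundance pipeline
#'
#' Executes simulate (scenario mode) or load (FASTQ mode), then
#' preprocess, subsample, species-tag, pool, cluster, filter, additivity
#' and parental-bias stages, returning all intermediate and final
#' objects plus a manifest of parameters, sub-seeds and per-stage record
#' counts. Identical config and seed reproduce identical tables.
#'
#' @param config a [pipeline_config()]
#' @return list with elements genomes, reads, table (filtered cluster
#'   table), records, curve, fits, slope_test, plane, manifest
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  codes <- config$codes
  roles <- c("maternal", "paternal", "tetraploid")

  genomes <- NULL
  if (!is.null(config$scenario)) {
    sc <- config$scenario
    genomes <- run_stage("simulate", {
      parents <- simulate_parents(
        n_families = sc$n_families,
        abundance_exponent = sc$abundance_exponent,
        divergence = sc$divergence,
        c_value_bp = sc$c_value_bp,
        seed = seeds[["simulate"]],
        unit_length = sc$unit_length %||% 500L,
        per_copy_divergence = sc$per_copy_divergence %||% 0.02,
        single_copy_fraction = sc$single_copy_fraction %||% 0.3,
        perturb_sd = sc$perturb_sd %||% 0.25,
        min_copies = sc$min_copies %||% 1,
        max_copies = sc$max_copies,
        codes = unname(codes[c("maternal", "paternal")]))
      tet <- apply_inheritance(parents$maternal, parents$paternal,
                               sc$inheritance, code = codes[["tetraploid"]])
      list(maternal = parents$maternal, paternal = parents$paternal,
           tetraploid = tet)
    })
    c_values <- vapply(genomes, function(g) g$c_value_bp, numeric(1))
  } else {
    c_values <- unlist(config$c_values[roles])
    names(c_values) <- roles
  }

  raw <- run_stage("reads", {
    if (!is.null(genomes)) {
      # oversample so that quality filtering + subsampling still reach
      # the target genome proportion
      lapply(genomes, generate_reads,
             proportion = min(1, config$proportion * 1.5),
             read_length = config$read_length,
             error_rate = config$scenario$error_rate %||% 0.01,
             seed = seeds[["reads"]])
    } else {
      stats::setNames(
        lapply(roles, function(r) read_fastq(config$fastq[[r]])), roles)
    }
  })

  prepped <- run_stage("preprocess", lapply(
    raw, preprocess_reads, min_phred = config$min_phred,
    max_n = config$max_n, target_length = config$read_length))

  sub <- run_stage("subsample", {
    out <- lapply(roles, function(r) {
      subsample_reads(prepped[[r]], c_value_bp = c_values[[r]],
                      proportion = config$proportion,
                      seed = seeds[["subsample"]])
    })
    stats::setNames(out, roles)
  })

  tagged <- run_stage("tag", {
    out <- lapply(roles, function(r) tag_species(sub[[r]], codes[[r]]))
    stats::setNames(out, roles)
  })

  pooled <- run_stage("pool", do.call(pool_reads, unname(tagged)))

  graph <- run_stage("cluster", build_similarity_graph(
    pooled, k = config$cluster$k,
    min_identity = config$cluster$min_identity,
    min_coverage = config$cluster$min_coverage,
    min_shared_kmers = config$cluster$min_shared_kmers))
  partition <- run_stage("cluster", partition_graph(
    graph, seed = seeds[["cluster"]],
    min_split_size = config$cluster$min_split_size))
  table_raw <- run_stage("cluster",
                         tabulate_clusters(partition, unname(codes)))

  if (!is.null(config$filters$contaminants)) {
    table_raw <- run_stage("filter", flag_contaminants(
      table_raw, pooled, config$filters$contaminants,
      min_fraction = config$filters$contaminant_min_fraction))
  }
  design <- cross_design(codes[["maternal"]], codes[["paternal"]],
                         codes[["tetraploid"]])
  table <- run_stage("filter", apply_filters(
    table_raw, design, min_reads = config$filters$min_reads,
    require_all_species = config$filters$require_all_species,
    keep_parents_only = config$filters$keep_parents_only))

  records <- run_stage("additivity", deviation_table(table, design))
  curve <- if (nrow(records)) run_stage("additivity",
                                        cumulative_curve(records)) else NULL

  min_reads <- config$filters$min_reads
  fit_m <- tryCatch(fit_parent_regression(records, "maternal", min_reads),
                    error = function(e) NULL)
  fit_p <- tryCatch(fit_parent_regression(records, "paternal", min_reads),
                    error = function(e) NULL)
  stest <- tryCatch(slope_equality_test(records, design, min_reads),
                    error = function(e) NULL)
  plane <- tryCatch(fit_joint_plane(records, min_reads),
                    error = function(e) NULL)

  manifest <- list(
    package = "polyrep",
    version = as.character(utils::packageVersion("polyrep")),
    seed = config$seed, stage_seeds = as.list(seeds),
    codes = as.list(codes), c_values = as.list(c_values),
    proportion = config$proportion, read_length = config$read_length,
    min_phred = config$min_phred, max_n = config$max_n,
    cluster = config$cluster,
    filters = config$filters[c("min_reads", "require_all_species",
                               "keep_parents_only")],
    counts = list(
      raw_reads = vapply(raw, length, integer(1)),
      preprocessed = vapply(prepped, length, integer(1)),
      subsampled = vapply(sub, length, integer(1)),
      graph_edges = nrow(graph$edges),
      clusters_raw = nrow(table_raw),
      clusters_retained = nrow(table),
      clusters_removed = nrow(filter_log(table))
    )
  )
  list(genomes = genomes, reads = tagged, pooled = pooled, graph = graph,
       table_raw = table_raw, table = table, design = design,
       records = records, curve = curve,
       fits = list(maternal = fit_m, paternal = fit_p),
       slope_test = stest, plane = plane, manifest = manifest)
}

#' Write pipeline outputs to a directory
#'
#' Emits clusters.tsv (per-species counts, flags, filter annotations),
#' membership.tsv (read -> cluster), deviation.tsv (additivity records
#' and the cumulative curve), report.json (fits, slope test, manifest)
#' and, when the cluster table is non-empty, the three figures:
#' fig2_deviation (cumulative deviation curve), fig3_regressions
#' (two parental log-log regressions), fig4_plane (static projection of
#' the joint plane fit). Tables and JSON are byte-stable for a fixed
#' config and seed.
#'
#' @param results list from [run_pipeline()]
#' @param outdir output directory (created if needed)
#' @param figures write PNG figures (default TRUE)
#' @return character vector of written paths, invisibly
#' @export
write_outputs <- function(results, outdir, figures = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, 2) != 0) stop("output directory is not writable")
  written <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
  }
  tab <- results$table_raw
  retained <- results$table
  log <- filter_log(retained)
  tab$filter_reason <- log$reason[match(tab$cluster_id, log$cluster_id)]
  tab$retained <- tab$cluster_id %in% retained$cluster_id
  tab$present_in <- retained$present_in[match(tab$cluster_id,
                                              retained$cluster_id)]
  tab$usable <- retained$usable[match(tab$cluster_id, retained$cluster_id)]
  wtsv(as.data.frame(tab), "clusters.tsv")

  members <- cluster_members(results$table_raw)
  if (!is.null(members) && length(members)) {
    wtsv(data.frame(
      read_id = unlist(members, use.names = FALSE),
      cluster_id = rep.int(names(members), lengths(members))),
      "membership.tsv")
  }
  if (!is.null(results$curve)) wtsv(as.data.frame(results$curve), "deviation.tsv")

  report <- list(
    fits = lapply(results$fits, function(f) if (is.null(f)) NULL else unclass(f)),
    slope_test = if (is.null(results$slope_test)) NULL else
      unclass(results$slope_test),
    plane = if (is.null(results$plane)) NULL else {
      p <- unclass(results$plane); p$se <- as.list(p$se); p
    },
    error_variance_pooling = "stacked two-group model (shared residual variance)",
    manifest = results$manifest
  )
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  written <- c(written, report_path)

  if (figures) {
    if (is.null(results$curve) || nrow(results$table) == 0) {
      warning("empty cluster table: figures skipped")
    } else {
      written <- c(written,
                   plot_deviation_curve(results$curve,
                                        file.path(outdir, "fig2_deviation.png")),
                   plot_parent_regressions(results$records, results$fits,
                                           file.path(outdir, "fig3_regressions.png")),
                   if (!is.null(results$plane))
                     plot_joint_plane(results$records, results$plane,
                                      file.path(outdir, "fig4_plane.png")))
    }
  }
  invisible(written)
}

#' Plot a cumulative deviation curve
#' @param curve a deviation_curve
#' @param path output PNG path
#' @return `path`, invisibly
#' @export
plot_deviation_curve <- function(curve, path) {
  grDevices::png(path, width = 1400, height = 900, res = 150)
  on.exit(grDevices::dev.off())
  ok <- !is.na(curve$ln_cum_E)
  graphics::plot(curve$ln_cum_E[ok], curve$cum_D[ok], type = "l", lwd = 2,
                 col = "steelblue4",
                 xlab = "ln cumulative expected cluster size",
                 ylab = "cumulative deviation from expectation (reads)",
                 main = "Repeat abundance deviation from parental additivity")
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(path)
}

#' Plot the two parental log-log regressions
#' @param records deviation records
#' @param fits list with maternal and paternal regression_fit (or NULL)
#' @param path output PNG path
#' @param min_count positivity threshold used for plotting (default 10)
#' @return `path`, invisibly
#' @export
plot_parent_regressions <- function(records, fits, path, min_count = 10L) {
  grDevices::png(path, width = 1200, height = 1000, res = 150)
  on.exit(grDevices::dev.off())
  km <- records$m >= min_count & records$t >= min_count
  kp <- records$p >= min_count & records$t >= min_count
  xs <- log(c(records$m[km], records$p[kp]))
  ys <- log(c(records$t[km], records$t[kp]))
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = "ln parental cluster size (reads)",
                 ylab = "ln tetraploid cluster size (reads)",
                 main = "Parental contributions to tetraploid cluster size")
  graphics::points(log(records$m[km]), log(records$t[km]),
                   col = "dodgerblue3", pch = 16, cex = 0.8)
  graphics::points(log(records$p[kp]), log(records$t[kp]),
                   col = "firebrick3", pch = 17, cex = 0.8)
  if (!is.null(fits$maternal))
    graphics::abline(fits$maternal$intercept, fits$maternal$slope,
                     col = "dodgerblue3", lwd = 2)
  if (!is.null(fits$paternal))
    graphics::abline(fits$paternal$intercept, fits$paternal$slope,
                     col = "firebrick3", lwd = 2)
  graphics::legend("topleft", legend = c("maternal", "paternal"),
                   col = c("dodgerblue3", "firebrick3"), pch = c(16, 17),
                   lwd = 2, bty = "n")
  invisible(path)
}

#' Static projection of the joint two-parent regression plane
#' @param records deviation records
#' @param plane a plane_fit
#' @param path output PNG path
#' @param min_count positivity threshold (default 10)
#' @return `path`, invisibly
#' @export
plot_joint_plane <- function(records, plane, path, min_count = 10L) {
  grDevices::png(path, width = 1200, height = 1000, res = 150)
  on.exit(grDevices::dev.off())
  keep <- records$m >= min_count & records$p >= min_count &
    records$t >= min_count
  xm <- log(records$m[keep]); xp <- log(records$p[keep])
  y <- log(records$t[keep])
  gx <- seq(min(xm), max(xm), length.out = 20)
  gy <- seq(min(xp), max(xp), length.out = 20)
  z <- outer(gx, gy, function(a, b)
    plane$intercept + plane$b_maternal * a + plane$b_paternal * b)
  pm <- graphics::persp(gx, gy, z, theta = 35, phi = 22, expand = 0.7,
                        col = grDevices::adjustcolor("steelblue1", 0.35),
                        border = "grey70",
                        xlab = "ln maternal size", ylab = "ln paternal size",
                        zlab = "ln tetraploid size",
                        main = "Joint parental regression plane")
  pts <- grDevices::trans3d(xm, xp, y, pm)
  graphics::points(pts, pch = 16, col = "grey20", cex = 0.7)
  invisible(path)
}
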