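#' Per-cluster additivity deviation records
#'
#' For each retained cluster, the expected tetraploid cluster size under
#' strict additivity is the sum of the parental read counts, E = m + p,
#' and the deviation is D = t - E: positive D means repeat amplification
#' beyond expectation in the tetraploid, negative D repeat loss. All
#' arithmetic is exact integer arithmetic on read counts.
#'
#' @param table a filtered cluster_table
#' @param design a [cross_design()]
#' @return data.frame with columns cluster_id, m, p, t, E, D (one row
#'   per retained cluster, table order preserved)
#' @export
deviation_table <- function(table, design) {
  stopifnot(inherits(table, "cluster_table"), inherits(design, "cross_design"))
  check_design(table, design)
  m <- table[[design$maternal]]
  p <- table[[design$paternal]]
  t <- table[[design$tetraploid]]
  data.frame(cluster_id = table$cluster_id,
             m = m, p = p, t = t, E = m + p, D = t - (m + p),
             stringsAsFactors = FALSE)
}

#' Cumulative deviation curve
#'
#' Ranks clusters from smallest to largest expected size and accumulates
#' expectation and deviation, giving the curve that visualizes repeat
#' dynamics across the cluster-size range: a near-flat signed curve means
#' additivity, a rising tail genome upsizing driven by large repeats, a
#' falling tail downsizing. The signed cumulative deviation is primary
#' (only it can show loss); the absolute value is carried alongside for
#' reporting. The x position is the natural log of cumulative expected
#' size (undefined, NA, while the running sum is zero).
#'
#' @param records data.frame from [deviation_table()]
#' @param rank_by ranking key: expected size `"E"` (default),
#'   tetraploid size `"t"`, or combined size `"mpt"` (m + p + t)
#' @return an object of classes `deviation_curve` and `data.frame` with
#'   columns of `records` plus cum_E, cum_D, abs_cum_D, ln_cum_E
#' @export
cumulative_curve <- function(records, rank_by = c("E", "t", "mpt")) {
  rank_by <- match.arg(rank_by)
  if (is.null(records) || nrow(records) == 0L)
    stop("cannot build a deviation curve from zero records")
  key <- switch(rank_by, E = records$E, t = records$t,
                mpt = records$m + records$p + records$t)
  ord <- order(key, records$cluster_id, method = "radix")
  out <- records[ord, , drop = FALSE]
  out$cum_E <- cumsum(out$E)
  out$cum_D <- cumsum(out$D)
  out$abs_cum_D <- abs(out$cum_D)
  out$ln_cum_E <- ifelse(out$cum_E > 0, log(out$cum_E), NA_real_)
  rownames(out) <- NULL
  structure(out, rank_by = rank_by,
            class = c("deviation_curve", "data.frame"))
}

#' Genome-size deviation from parental expectation
#'
#' Percent difference between the observed tetraploid 1C genome size and
#' the additivity expectation (the sum of the parental 1C values):
#' `100 * (observed - expected) / expected`. Positive values are genome
#' upsizing, negative downsizing.
#'
#' @param observed_1C observed tetraploid 1C size (any unit)
#' @param expected_1C expected 1C size, same unit, > 0
#' @return percent deviation (numeric scalar or vector)
#' @examples
#' genome_size_deviation(5.3, 4.1)   # upsizing of around 29%
#' genome_size_deviation(5.2, 2.9 + 2.4)  # slight downsizing
#' @export
genome_size_deviation <- function(observed_1C, expected_1C) {
  if (any(expected_1C <= 0)) stop("expected 1C size must be positive")
  100 * (observed_1C - expected_1C) / expected_1C
}
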