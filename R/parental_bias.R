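# Closed-form OLS on a design matrix: coefficients, SEs, SSE.
# Solved via the normal equations with a symmetric solve; the matrix
# independence oracle in the tests goes through lm()/car instead.
ols_fit <- function(X, y) {
  XtX <- crossprod(X)
  qrX <- qr(XtX)
  if (qrX$rank < ncol(X))
    stop("design matrix is collinear (rank ", qrX$rank, " < ", ncol(X), ")")
  beta <- solve(qrX, crossprod(X, y))
  resid <- y - X %*% beta
  sse <- sum(resid^2)
  df <- length(y) - ncol(X)
  sigma2 <- if (df > 0) sse / df else NA_real_
  se <- sqrt(diag(solve(qrX)) * sigma2)
  list(beta = drop(beta), se = se, sse = sse, df = df, n = length(y))
}

#' Log-log regression of tetraploid on one parent's cluster size
#'
#' Ordinary least squares of ln(tetraploid count) on ln(parental count)
#' over clusters where both counts reach `min_count` (positivity: the
#' natural log requires positive counts; the default matches the
#' per-species presence threshold of the filtering stage). Slope 1 with
#' intercept near ln(1) would indicate the parent's repeats carried over
#' proportionally.
#'
#' @param records data.frame from [deviation_table()]
#' @param parent "maternal" (regress on m) or "paternal" (on p)
#' @param min_count inclusion threshold on the parent count and t
#'   (default 10)
#' @return object of class `regression_fit`: slope, intercept, their
#'   standard errors, residual_sum_squares, r_squared, n
#' @export
fit_parent_regression <- function(records, parent = c("maternal", "paternal"),
                                  min_count = 10L) {
  parent <- match.arg(parent)
  x_raw <- if (parent == "maternal") records$m else records$p
  keep <- x_raw >= max(min_count, 1L) & records$t >= max(min_count, 1L)
  x <- log(x_raw[keep])
  y <- log(records$t[keep])
  n <- length(x)
  if (n < 3L) stop("need at least 3 usable clusters, have ", n)
  if (stats::var(x) == 0) stop("zero variance in the predictor")
  fit <- ols_fit(cbind(1, x), y)
  tss <- sum((y - mean(y))^2)
  structure(
    list(parent = parent, slope = unname(fit$beta[2]),
         intercept = unname(fit$beta[1]),
         se_slope = unname(fit$se[2]), se_intercept = unname(fit$se[1]),
         residual_sum_squares = fit$sse,
         r_squared = if (tss > 0) 1 - fit$sse / tss else NA_real_,
         n = n),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "ln(t) ~ ln(%s): slope %.4f (SE %.4f), intercept %.4f (SE %.4f), R^2 %.3f, n = %d\n",
    substr(x$parent, 1, 1), x$slope, x$se_slope, x$intercept, x$se_intercept,
    x$r_squared, x$n))
  invisible(x)
}

#' F-test for equality of the two parental regression slopes
#'
#' Stacks the maternal and paternal log-log datasets (each cluster
#' contributes one observation per parent) and fits the full model
#' ln t = b0 + b1 ln x + b2 I + b3 (ln x * I), where I indicates the
#' paternal half, against the restricted model with b3 = 0 (common
#' slope). The test statistic is the extra-sum-of-squares F with 1 and
#' n_total - 4 degrees of freedom — the standard general-linear-
#' hypothesis realization of a two-slope comparison, and the schema
#' (Sum of Sq., F, p) of the published analysis. Only clusters with all
#' three counts at or above `min_count` enter (both logs must exist);
#' the number excluded is reported.
#'
#' @param records data.frame from [deviation_table()]
#' @param design a [cross_design()] (used for labeling)
#' @param min_count inclusion threshold on m, p and t (default 10)
#' @return object of class `slope_test`: sum_of_squares, f_stat,
#'   p_value, df (length 2), n_clusters, n_total, per-parent slopes
#' @export
slope_equality_test <- function(records, design = NULL, min_count = 10L) {
  keep <- records$m >= max(min_count, 1L) &
    records$p >= max(min_count, 1L) &
    records$t >= max(min_count, 1L)
  r <- records[keep, , drop = FALSE]
  nc <- nrow(r)
  if (nc < 3L)
    stop("need at least 3 clusters usable for both parents, have ", nc)
  y <- c(log(r$t), log(r$t))
  x <- c(log(r$m), log(r$p))
  g <- rep(c(0, 1), each = nc)
  n_total <- 2L * nc
  full <- ols_fit(cbind(1, x, g, x * g), y)
  restricted <- ols_fit(cbind(1, x, g), y)
  ss <- max(restricted$sse - full$sse, 0)
  df2 <- n_total - 4L
  if (df2 < 1L) stop("insufficient observations for the F-test")
  f <- ss / (full$sse / df2)
  structure(
    list(sum_of_squares = ss, f_stat = f,
         p_value = stats::pf(f, 1, df2, lower.tail = FALSE),
         df = c(1L, df2), n_clusters = nc, n_total = n_total,
         slope_maternal = unname(full$beta[2]),
         slope_paternal = unname(full$beta[2] + full$beta[4]),
         sse_full = full$sse, sse_restricted = restricted$sse,
         n_excluded = sum(!keep),
         maternal_code = design$maternal %||% NA_character_,
         paternal_code = design$paternal %||% NA_character_,
         tetraploid_code = design$tetraploid %||% NA_character_),
    class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf(
    "slope equality test: Sum of Sq. = %.4f, F(%d, %d) = %.4f, p = %.4g\n",
    x$sum_of_squares, x$df[1], x$df[2], x$f_stat, x$p_value))
  cat(sprintf("  maternal slope %.4f, paternal slope %.4f, %d clusters (%d excluded)\n",
              x$slope_maternal, x$slope_paternal, x$n_clusters, x$n_excluded))
  invisible(x)
}

#' Joint two-parent regression plane
#'
#' OLS of ln(t) on ln(m) and ln(p) jointly, over clusters positive in
#' all three species — the plane fitted through the three-dimensional
#' cluster-size scatter.
#'
#' @param records data.frame from [deviation_table()]
#' @param min_count inclusion threshold on all three counts (default 10)
#' @return object of class `plane_fit`: intercept, b_maternal,
#'   b_paternal with SEs, residual_sum_squares, r_squared, n
#' @export
fit_joint_plane <- function(records, min_count = 10L) {
  keep <- records$m >= max(min_count, 1L) &
    records$p >= max(min_count, 1L) &
    records$t >= max(min_count, 1L)
  r <- records[keep, , drop = FALSE]
  if (nrow(r) < 4L) stop("need at least 4 usable clusters, have ", nrow(r))
  xm <- log(r$m); xp <- log(r$p); y <- log(r$t)
  if (stats::var(xm) == 0 || stats::var(xp) == 0 ||
      abs(stats::cor(xm, xp)) >= 1 - 1e-12)
    stop("ln(m) and ln(p) are collinear; the plane is not identifiable")
  fit <- ols_fit(cbind(1, xm, xp), y)
  tss <- sum((y - mean(y))^2)
  structure(
    list(intercept = unname(fit$beta[1]), b_maternal = unname(fit$beta[2]),
         b_paternal = unname(fit$beta[3]),
         se = stats::setNames(fit$se, c("intercept", "b_maternal", "b_paternal")),
         residual_sum_squares = fit$sse,
         r_squared = if (tss > 0) 1 - fit$sse / tss else NA_real_,
         n = nrow(r)),
    class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf(
    "ln(t) ~ ln(m) + ln(p): b_m %.4f (SE %.4f), b_p %.4f (SE %.4f), R^2 %.3f, n = %d\n",
    x$b_maternal, x$se["b_maternal"], x$b_paternal, x$se["b_paternal"],
    x$r_squared, x$n))
  invisible(x)
}
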