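# Per-sample aggregation and depth-profile statistics: morphotype fractions,
# volume percentiles, the morphotype-weighted mean volume feeding the carbon
# density, one-way ANOVA depth trends, bootstrap intervals, and the FM/SEM
# concordance check.

SUMMARY_PROBS <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)

#' Summarize one sample of corrected cell measurements
#'
#' Computes morphotype fractions, per-morphotype mean, median and percentile
#' volumes (linear interpolation between order statistics), and the
#' morphotype-weighted mean volume
#' \eqn{\bar{V} = \sum_m f_m \bar{V}_m} used as the denominator of the
#' cell-specific carbon density.
#'
#' @param cells Data.frame for a single sample with `morphotype` and a
#'   volume column.
#' @param volume_col Name of the volume column (default
#'   `"volume_corrected_um3"`).
#' @return A `sample_summary`: list with `sample_id`, `depth_mbsf`,
#'   `n_cells`, `fractions` (named over all three morphotypes),
#'   `mean_volume`, `median_volume` (named, `NA` for absent morphotypes),
#'   `percentiles` (probability x morphotype matrix) and
#'   `weighted_mean_volume`.
#' @export
summarize_sample <- function(cells, volume_col = "volume_corrected_um3") {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) stop_degenerate_sample("no cells in sample")
  if (is.null(cells[[volume_col]]) || is.null(cells$morphotype)) {
    stop_schema(sprintf("need 'morphotype' and '%s' columns", volume_col))
  }
  v <- cells[[volume_col]]
  check_positive(v, volume_col)
  counts <- vapply(MORPHOTYPES, function(m) sum(cells$morphotype == m), numeric(1))
  fractions <- counts / sum(counts)
  stat_by <- function(fun) {
    vapply(MORPHOTYPES, function(m) {
      if (counts[[m]] == 0) NA_real_ else fun(v[cells$morphotype == m])
    }, numeric(1))
  }
  mean_volume <- stat_by(mean)
  median_volume <- stat_by(stats::median)
  percentiles <- vapply(MORPHOTYPES, function(m) {
    if (counts[[m]] == 0) rep(NA_real_, length(SUMMARY_PROBS))
    else stats::quantile(v[cells$morphotype == m], probs = SUMMARY_PROBS,
                         names = FALSE, type = 7)
  }, numeric(length(SUMMARY_PROBS)))
  rownames(percentiles) <- paste0("p", SUMMARY_PROBS * 100)
  present <- fractions > 0
  structure(list(
    sample_id = if (!is.null(cells$sample_id)) cells$sample_id[1] else NA_character_,
    depth_mbsf = if (!is.null(cells$depth_mbsf)) cells$depth_mbsf[1] else NA_real_,
    n_cells = nrow(cells),
    fractions = fractions,
    mean_volume = mean_volume,
    median_volume = median_volume,
    percentiles = percentiles,
    weighted_mean_volume = sum(fractions[present] * mean_volume[present])),
    class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("Sample %s (%.2f mbsf): %d cells\n",
              x$sample_id, x$depth_mbsf, x$n_cells))
  cat("  fractions:", paste(sprintf("%s %.2f", names(x$fractions), x$fractions),
                            collapse = ", "), "\n")
  cat(sprintf("  weighted mean volume: %.4g um^3\n", x$weighted_mean_volume))
  invisible(x)
}

#' Summarize every sample in a measurement table
#'
#' @param cells Corrected measurement table spanning one or more samples
#'   (split on `sample_id`).
#' @inheritParams summarize_sample
#' @return Named list of `sample_summary` objects, ordered by depth.
#' @export
summarize_samples <- function(cells, volume_col = "volume_corrected_um3") {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) == 0L) stop_degenerate_sample("empty measurement table")
  out <- lapply(split(cells, cells$sample_id), summarize_sample,
                volume_col = volume_col)
  out[order(vapply(out, `[[`, numeric(1), "depth_mbsf"))]
}

#' Flatten sample summaries to a data.frame
#'
#' @param x A `sample_summary` or list of them.
#' @param ... Unused.
#' @return One row per sample: id, depth, cell count, fractions, per-
#'   morphotype mean/median volumes and the weighted mean volume.
#' @export
as.data.frame.sample_summary <- function(x, ...) {
  row <- data.frame(sample_id = x$sample_id, depth_mbsf = x$depth_mbsf,
                    n_cells = x$n_cells)
  for (m in MORPHOTYPES) {
    row[[paste0("frac_", m)]] <- x$fractions[[m]]
    row[[paste0("mean_vol_", m)]] <- x$mean_volume[[m]]
    row[[paste0("median_vol_", m)]] <- x$median_volume[[m]]
  }
  row$weighted_mean_volume <- x$weighted_mean_volume
  row
}

summaries_to_df <- function(summaries) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, as.data.frame))
}

#' One-way ANOVA for a depth trend in cell volumes
#'
#' Fixed-effects one-way ANOVA across depth groups. Volumes are
#' log10-transformed by default because within-sample biovolumes are
#' lognormal-like; set `log_transform = FALSE` to test the raw values.
#'
#' @param groups List (one element per depth/sample) of numeric volume
#'   vectors; at least 2 groups with at least 2 observations each.
#' @param log_transform Apply `log10` before testing (default `TRUE`).
#' @return A `trend_anova`: list with `statistic` (F), `df_between`,
#'   `df_within` and `p_value`.
#' @export
depth_trend_anova <- function(groups, log_transform = TRUE) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_invalid_design("need at least two depth groups")
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop_invalid_design("every group needs at least two observations")
  }
  y <- unlist(groups, use.names = FALSE)
  if (!is.numeric(y) || any(!is.finite(y))) {
    stop_invalid_measurement("volumes must be finite")
  }
  if (log_transform) {
    check_positive(y, "volumes (log10 transform)")
    y <- log10(y)
  }
  g <- factor(rep(seq_along(groups), sizes))
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  structure(list(statistic = unname(fit$statistic),
                 df_between = unname(fit$parameter[1]),
                 df_within = unname(fit$parameter[2]),
                 p_value = if (is.nan(fit$p.value)) 1 else unname(fit$p.value),
                 log_transform = log_transform),
            class = "trend_anova")
}

#' @export
print.trend_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA%s: F = %.4g on %d and %d df, p = %.3g\n",
              if (x$log_transform) " (log10 volumes)" else "",
              x$statistic, x$df_between, x$df_within, x$p_value))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric percentile bootstrap for the mean or median. Reproducible
#' when a seed is supplied; the caller's RNG state is left untouched.
#'
#' @param values Non-empty numeric vector.
#' @param statistic `"mean"` or `"median"`.
#' @param n_reps Bootstrap replicates, at least 100 (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @return List with `lower`, `upper`, `estimate`, `level`, `n_reps`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "median"),
                         n_reps = 1000, level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L || !is.numeric(values) || any(!is.finite(values))) {
    stop_degenerate_sample("'values' must be a non-empty finite numeric vector")
  }
  if (n_reps < 100) stop_configuration("'n_reps' must be at least 100")
  stat_fun <- switch(statistic, mean = mean, median = stats::median)
  n <- length(values)
  reps <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_reps, replace = TRUE), nrow = n)
    if (statistic == "mean") colMeans(matrix(values[idx], nrow = n))
    else apply(matrix(values[idx], nrow = n), 2, stats::median)
  })
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(lower = ci[1], upper = ci[2], estimate = stat_fun(values),
       level = level, n_reps = n_reps)
}

#' Concordance between paired volume determinations
#'
#' For paired volumes of the same cells measured by two modalities (e.g.
#' corrected FM vs corrected SEM), reports the mean log10 ratio B/A and the
#' least-squares slope of B on A through the origin. The two methods are
#' declared concordant when the mean log-ratio lies within `band`.
#'
#' @param volume_a,volume_b Paired positive volume vectors of equal length,
#'   at least 2 pairs.
#' @param band Half-width of the concordance band on the mean log10 ratio
#'   (default 0.05, i.e. agreement within ~12% on the geometric mean).
#' @return List with `mean_log10_ratio`, `slope`, `n_pairs`, `concordant`.
#' @export
modality_concordance <- function(volume_a, volume_b, band = 0.05) {
  if (length(volume_a) != length(volume_b) || length(volume_a) < 2L) {
    stop_invalid_design("need at least two pairs of equal length")
  }
  check_positive(volume_a, "volume_a")
  check_positive(volume_b, "volume_b")
  mlr <- mean(log10(volume_b / volume_a))
  slope <- sum(volume_a * volume_b) / sum(volume_a^2)
  list(mean_log10_ratio = mlr, slope = slope, n_pairs = length(volume_a),
       concordant = abs(mlr) <= band)
}
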