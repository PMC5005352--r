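# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: textbook sums-of-squares for the one-way ANOVA,
# manual linear interpolation for percentiles, and a plain geometric mean.

anova_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  grand <- mean(y)
  ss_between <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_within <- sum(unlist(lapply(groups, function(g) (g - mean(g))^2)))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = f, df1 = k - 1, df2 = n - k,
       p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}

geomean <- function(x) exp(mean(log(x)))

# Classify + volume + correct on an observed measurement table.
correct_observed <- function(measurements, table = default_correction_table()) {
  cells <- classify_cells(read_measurements(measurements))
  correct_cells(cell_volume(cells), table)
}
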