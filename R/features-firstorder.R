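# First-order features. The 14 intensity-based statistics are computed on
# the continuous (pre-discretization) ROI values — which is why they are
# structurally invariant to bin width — while the two intensity-histogram
# features (Entropy, Uniformity) use the discretized level histogram.
# Percentiles use the linear-interpolation convention (stats::quantile
# type 7). Kurtosis is reported in Pearson (non-excess) form, i.e. excess
# kurtosis + 3.

#' First-order features of a map restricted to its ROI
#'
#' @param map A [quant_map()] (possibly filtered).
#' @param mask A [roi_mask()] congruent with `map`.
#' @param d The [discretize_roi()] result used for the histogram features.
#' @return A tibble with 16 rows (`feature_class = "firstorder"`).
#' @export
firstorder_features <- function(map, mask, d) {
  x <- roi_values(map, mask)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  q <- stats::quantile(x, c(.10, .25, .75, .90), names = FALSE, type = 7)
  robust <- x[x >= q[1] & x <= q[4]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else NA_real_
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else NA_real_
  lv <- d$levels[!is.na(d$levels)]
  p <- tabulate(lv, nbins = d$n_levels) / length(lv)
  p <- p[p > 0]
  vals <- c(
    Mean = mu,
    Variance = m2,
    Skewness = skew,
    Kurtosis = kurt,
    Median = stats::median(x),
    Minimum = min(x),
    `10Percentile` = q[1],
    `90Percentile` = q[4],
    Maximum = max(x),
    InterquartileRange = q[3] - q[2],
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    Energy = sum(x^2),
    RootMeanSquared = sqrt(mean(x^2)),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2)
  )
  tibble::tibble(feature_class = "firstorder",
                 feature_name = names(vals),
                 value = unname(vals))
}
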