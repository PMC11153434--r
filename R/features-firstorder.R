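# First-order intensity statistics. All moments are computed on the raw SUV
# values in the ROI; Entropy and Uniformity use the fixed-bin-width
# discretized probabilities. Percentiles interpolate linearly between order
# statistics. Skewness and kurtosis of a constant ROI are defined as 0
# (degenerate-moment convention of the reference catalog); kurtosis is not
# excess kurtosis.

.firstorder_features <- function(image, roi, disc) {
  x <- image$data[roi$data]
  n <- length(x)
  vv <- voxel_volume(image)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p <- tabulate(disc$labels[roi$data], nbins = disc$n_levels) / n
  pq <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  inb <- x[x >= pq[1] & x <= pq[4]]
  energy <- sum(x^2)
  list(
    X10Percentile = pq[1],
    X90Percentile = pq[4],
    Energy = energy,
    Entropy = -sum(p * log2(p + .eps)),
    InterquartileRange = pq[3] - pq[2],
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Mean = mu,
    Median = stats::median(x),
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation =
      if (length(inb)) mean(abs(inb - mean(inb))) else 0,
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = vv * energy,
    Uniformity = sum(p^2),
    Variance = m2)
}
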