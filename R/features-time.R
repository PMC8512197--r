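#' Time-domain features of a preprocessed record
#'
#' Nine scalar statistics of the z-scored amplitude trace: median, mean
#' absolute deviation (about the mean), first and third quartiles,
#' interquartile range, skewness (g1 = m3 / m2^1.5), kurtosis (non-excess,
#' m4 / m2^2, Gaussian = 3), Shannon energy, and zero-crossing rate.
#'
#' Shannon energy is the envelope-emphasising measure common in heart-sound
#' work: -(1/N) sum(x^2 * ln x^2), with 0 * ln 0 taken as 0. The
#' zero-crossing rate counts strict sign changes (x_i * x_{i+1} < 0) over
#' N - 1 adjacent pairs, so it lies in [0, 1]. Quartiles use linear
#' interpolation between order statistics (R's default quantile type 7).
#'
#' @param rec A `pcg_record` (or any numeric vector for `x`).
#' @return A named list with the nine features, in canonical order.
#' @export
compute_time_features <- function(rec) {
  x <- if (is_pcg_record(rec)) rec$samples else as.numeric(rec)
  n <- length(x)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  x2 <- x^2
  lx2 <- ifelse(x2 > 0, log(x2), 0)
  list(
    median = qs[2],
    mean_absolute_deviation = mean(abs(x - mu)),
    q1 = qs[1],
    q3 = qs[3],
    iqr = qs[3] - qs[1],
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2,
    shannon_energy = -mean(x2 * lx2),
    zero_crossing_rate = sum(x[-n] * x[-1] < 0) / (n - 1)
  )
}
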