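#' Welch power spectral density of a preprocessed record
#'
#' Welch's averaged-periodogram estimate: 1024-sample Hamming-windowed
#' segments with 50% overlap, one-sided. At the canonical 2 kHz rate the
#' frequency resolution is ~1.95 Hz and the grid spans 0-1000 Hz. The DC bin
#' is retained in the estimate but excluded by downstream feature
#' computations (after z-scoring it carries no murmur information).
#'
#' @param rec A `pcg_record`, or a numeric vector with `rate` given.
#' @param rate Sampling rate in Hz (taken from the record if omitted).
#' @param nfft Segment length (default 1024).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return A list with `frequencies` (Hz, ascending) and `power`
#'   (non-negative density per bin), class `psd_estimate`.
#' @export
estimate_psd <- function(rec, rate = NULL, nfft = 1024, overlap = 0.5) {
  if (is_pcg_record(rec)) {
    x <- rec$samples
    rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("estimate_psd: `rate` required for plain vectors",
                            call. = FALSE)
  }
  n <- length(x)
  if (n < nfft) stop("estimate_psd: record shorter than one segment",
                     call. = FALSE)
  hop <- as.integer(round(nfft * (1 - overlap)))
  starts <- seq(1L, n - nfft + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1)) # Hamming
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w,
                   numeric(nfft))
  spec <- stats::mvfft(frames)
  half <- nfft %/% 2L + 1L
  pxx <- rowMeans(Mod(spec[seq_len(half), , drop = FALSE])^2)
  # one-sided density scaling (interior bins doubled)
  scale <- 1 / (rate * sum(w^2))
  pxx <- pxx * scale
  pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
  structure(
    list(
      frequencies = (seq_len(half) - 1) * rate / nfft,
      power = pxx
    ),
    class = "psd_estimate"
  )
}

#' Frequency-domain features from a PSD estimate
#'
#' Five spectral summaries computed on the DC-excluded, sum-normalised power
#' distribution p(f): normalised spectral entropy (-sum p ln p / ln #bins,
#' in \[0, 1\]); the dominant frequency (argmax of p, lowest frequency wins
#' ties); the dominant frequency magnitude (max p); the dominant frequency
#' ratio (power fraction within +/-5% of the dominant frequency, at least
#' +/-1 bin); and the bandwidth (power-weighted spectral spread around the
#' spectral centroid, in Hz).
#'
#' @param psd A `psd_estimate` from [estimate_psd()].
#' @return Named list of the five features, in canonical order.
#' @export
compute_frequency_features <- function(psd) {
  stopifnot(inherits(psd, "psd_estimate"))
  keep <- psd$frequencies > 0
  f <- psd$frequencies[keep]
  pw <- psd$power[keep]
  tot <- sum(pw)
  if (!is.finite(tot) || tot <= 0) {
    stop("degenerate spectrum: total power is zero", call. = FALSE)
  }
  p <- pw / tot
  nb <- length(p)
  plogp <- ifelse(p > 0, p * log(p), 0)
  entropy <- -sum(plogp) / log(nb)
  i_dom <- which.max(p) # which.max returns the first (lowest-frequency) tie
  f_dom <- f[i_dom]
  df <- f[2] - f[1]
  half_width <- max(0.05 * f_dom, df)
  in_nbhd <- abs(f - f_dom) <= half_width + 1e-9
  centroid <- sum(p * f)
  list(
    spectral_entropy = entropy,
    dominant_frequency_value = f_dom,
    dominant_frequency_magnitude = p[i_dom],
    dominant_frequency_ratio = sum(p[in_nbhd]),
    bandwidth = sqrt(sum(p * (f - centroid)^2))
  )
}
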