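#' MFCC configuration
#'
#' Framing and filterbank parameters for [mfcc_features()], chosen for a
#' 2 kHz signal whose information lives below 1 kHz: 256-sample (128 ms)
#' frames resolve the low-frequency murmur bands, and 26 triangular mel
#' filters over 0-1000 Hz keep at least two FFT bins under every filter.
#' No pre-emphasis is applied (a speech-specific high-frequency boost that
#' is inappropriate for heart sounds).
#'
#' @param frame_length Samples per frame (default 256).
#' @param hop Hop between frame starts in samples (default 128).
#' @param n_mel_filters Number of triangular mel filters (default 26).
#' @param n_coefficients Number of retained cepstral coefficients (13).
#' @param log_floor Floor applied to filterbank energies before the log.
#' @return A list of class `mfcc_config`.
#' @export
mfcc_config <- function(frame_length = 256, hop = 128, n_mel_filters = 26,
                        n_coefficients = 13, log_floor = 1e-10) {
  stopifnot(hop <= frame_length, n_mel_filters >= n_coefficients)
  structure(
    list(
      frame_length = as.integer(frame_length),
      hop = as.integer(hop),
      n_mel_filters = as.integer(n_mel_filters),
      n_coefficients = as.integer(n_coefficients),
      log_floor = log_floor
    ),
    class = "mfcc_config"
  )
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank as a (n_filters x n_bins) matrix acting on the
# magnitude-squared half spectrum.
mel_filterbank <- function(n_filters, nfft, rate, f_low = 0, f_high = rate / 2) {
  n_bins <- nfft %/% 2L + 1L
  f_bins <- (seq_len(n_bins) - 1) * rate / nfft
  mel_pts <- seq(hz_to_mel(f_low), hz_to_mel(f_high), length.out = n_filters + 2)
  f_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_filters, n_bins)
  for (j in seq_len(n_filters)) {
    fl <- f_pts[j]; fc <- f_pts[j + 1]; fr <- f_pts[j + 2]
    up <- (f_bins - fl) / (fc - fl)
    down <- (fr - f_bins) / (fr - fc)
    fb[j, ] <- pmax(0, pmin(up, down))
  }
  fb
}

# Orthonormal DCT-II matrix rows `rows` (0-based indices) acting on length-n
# vectors.
dct2_matrix <- function(rows, n) {
  k <- rows
  mat <- outer(k, seq_len(n) - 1, function(kk, nn) {
    cos(pi * (nn + 0.5) * kk / n)
  })
  scale <- ifelse(k == 0, sqrt(1 / n), sqrt(2 / n))
  mat * scale
}

#' Mel-frequency cepstral coefficients of a preprocessed record
#'
#' Per frame: Hamming window, magnitude-squared spectrum, triangular mel
#' filterbank energies over 0-1000 Hz, natural log with floor, orthonormal
#' DCT-II. Coefficients 1..13 are retained (the 0th, a pure loudness proxy,
#' is excluded; overall level is separately captured by the acoustic
#' loudness feature) and averaged over frames into one scalar each.
#'
#' @param rec A `pcg_record`, or a numeric vector with `rate`.
#' @param cfg An [mfcc_config()].
#' @param rate Sampling rate, taken from the record if omitted.
#' @return Named list `mfcc1` .. `mfcc13`.
#' @export
mfcc_features <- function(rec, cfg = mfcc_config(), rate = NULL) {
  if (is_pcg_record(rec)) {
    x <- rec$samples
    rate <- rec$rate
  } else {
    x <- as.numeric(rec)
    if (is.null(rate)) stop("mfcc_features: `rate` required", call. = FALSE)
  }
  nfft <- cfg$frame_length
  if (length(x) < nfft) {
    stop("mfcc_features: record shorter than one frame", call. = FALSE)
  }
  starts <- seq(1L, length(x) - nfft + 1L, by = cfg$hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w,
                   numeric(nfft))
  half <- nfft %/% 2L + 1L
  pow <- Mod(stats::mvfft(frames)[seq_len(half), , drop = FALSE])^2
  fb <- mel_filterbank(cfg$n_mel_filters, nfft, rate,
                       f_low = 0, f_high = min(1000, rate / 2))
  energies <- fb %*% pow # filters x frames
  log_e <- log(pmax(energies, cfg$log_floor))
  dct <- dct2_matrix(seq_len(cfg$n_coefficients), cfg$n_mel_filters)
  coefs <- dct %*% log_e # coefficients x frames
  out <- rowMeans(coefs)
  stats::setNames(as.list(out), paste0("mfcc", seq_len(cfg$n_coefficients)))
}
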