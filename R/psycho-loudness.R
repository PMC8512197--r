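# Psychoacoustic loudness and sharpness.
#
# The loudness model follows the Zwicker stationary-loudness structure:
# short-time spectra are integrated into 1-Bark-wide sliding critical bands
# on a 0.1-Bark grid, excitation above the Terhardt threshold in quiet is
# mapped to specific loudness N'(z) with the standard compressive law, and
# total loudness is the Bark integral of N'(z). The sone scale is fixed by
# the unit's definition: a 1 kHz pure tone at 40 dB SPL has loudness 1 sone.
# Inter-band masking slopes are not modelled (documented simplification);
# the 1-Bark sliding integration provides the critical-band smoothing.

# package-local cache for unit-anchor calibration constants
.pcg_cache <- new.env(parent = emptyenv())

#' Critical-band rate (Bark) of a frequency
#'
#' Zwicker's analytic approximation
#' `z = 13 atan(0.00076 f) + 3.5 atan((f / 7500)^2)`.
#'
#' @param f Frequency in Hz.
#' @return Critical-band rate in Bark.
#' @export
hz_to_bark <- function(f) {
  13 * atan(0.00076 * f) + 3.5 * atan((f / 7500)^2)
}

# inverse of hz_to_bark by monotone interpolation on a fixed table
bark_to_hz <- local({
  f_grid <- c(0, exp(seq(log(1), log(20000), length.out = 4000)))
  z_grid <- hz_to_bark(f_grid)
  function(z) stats::approx(z_grid, f_grid, xout = z, rule = 2)$y
})

#' Threshold in quiet (Terhardt)
#'
#' `3.64 (f/1000)^-0.8 - 6.5 exp(-0.6 ((f/1000) - 3.3)^2) + 1e-3 (f/1000)^4`
#' dB SPL — the smooth analytic hearing-threshold curve.
#'
#' @param f Frequency in Hz.
#' @return Threshold in dB SPL.
#' @export
threshold_in_quiet <- function(f) {
  fk <- pmax(f, 1) / 1000
  3.64 * fk^-0.8 - 6.5 * exp(-0.6 * (fk - 3.3)^2) + 1e-3 * fk^4
}

P0 <- 2e-5 # reference sound pressure, Pa

#' Map a preprocessed record to a calibrated sound-pressure signal
#'
#' Psychoacoustic models need SPL-referenced pressure input; stethoscope
#' recordings carry no absolute level, so the package adopts a fixed
#' convention: the unit-RMS z-scored record is assigned
#' `reference_level` dB SPL (default 60, conversational level). The signal
#' is then upsampled to the model rate.
#'
#' @param rec A `pcg_record`.
#' @param reference_level dB SPL assigned to unit-RMS input (default 60).
#' @param model_rate Analysis rate in Hz (default 16000; at least 8000).
#' @return A `calibrated_signal`: pressure samples in Pa at `model_rate`.
#' @export
calibrate <- function(rec, reference_level = 60, model_rate = 16000) {
  stopifnot_pcg(rec)
  if (model_rate < 8000) stop("model_rate must be >= 8000 Hz", call. = FALSE)
  frac <- ratio_integers(model_rate, rec$rate)
  x <- signal::resample(rec$samples, frac$p, frac$q)
  calibrated_signal(x / rms(x), model_rate, reference_level)
}

#' Construct a calibrated signal from an arbitrary waveform
#'
#' Scales `samples` so that its RMS pressure corresponds to
#' `reference_level` dB SPL re 20 uPa. Used by [calibrate()] and directly
#' by model-level analyses of test tones.
#'
#' @param samples Waveform (any scale).
#' @param rate Sampling rate in Hz.
#' @param reference_level RMS level in dB SPL.
#' @return A `calibrated_signal`.
#' @export
calibrated_signal <- function(samples, rate, reference_level = 60) {
  r <- rms(samples)
  target <- P0 * 10^(reference_level / 20)
  scaled <- if (r > 0) samples * (target / r) else samples
  structure(
    list(samples = scaled, rate = rate, reference_level = reference_level),
    class = "calibrated_signal"
  )
}

rms <- function(x) sqrt(mean(x^2))

#' Specific loudness pattern of a calibrated signal
#'
#' Frame-wise Zwicker-style specific loudness: per 64 ms Hamming frame the
#' power spectrum is integrated into 1-Bark-wide sliding critical bands on a
#' 0.1-Bark grid (0.1-24 Bark), excitation is compared with the Terhardt
#' threshold in quiet, and
#' `N'(z) = 0.08 (E_TQ/E_0)^0.23 ((0.5 + 0.5 E/E_TQ)^0.23 - 1)` (clamped at
#' zero below threshold) gives the specific loudness in sone/Bark.
#'
#' @param sig A `calibrated_signal`.
#' @param frame_sec Analysis frame length in seconds (default 0.064).
#' @return A `specific_loudness_pattern`: `bark_axis` (0.1-Bark grid) and a
#'   `specific_loudness` matrix (bands x frames), plus the model rate.
#' @export
specific_loudness <- function(sig, frame_sec = 0.064) {
  stopifnot(inherits(sig, "calibrated_signal"))
  rate <- sig$rate
  x <- sig$samples
  nfft <- 2^ceiling(log2(frame_sec * rate))
  if (length(x) < nfft) { # short test tones: single zero-padded frame
    x <- c(x, rep(0, nfft - length(x)))
  }
  hop <- nfft %/% 2L
  starts <- seq(1L, length(x) - nfft + 1L, by = hop)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(nfft - 1)) / (nfft - 1))
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1L)] * w,
                   numeric(nfft))
  half <- nfft %/% 2L + 1L
  # per-bin mean-square pressure (Pa^2), window-compensated, one-sided
  pow <- Mod(stats::mvfft(frames)[seq_len(half), , drop = FALSE])^2
  pow <- pow * (2 / sum(w)^2)
  pow[1, ] <- pow[1, ] / 2

  z_axis <- seq(0.1, 24, by = 0.1)
  key <- paste0("slmat_", rate, "_", nfft)
  if (is.null(.pcg_cache[[key]])) {
    f_bins <- (seq_len(half) - 1) * rate / nfft
    zb <- hz_to_bark(f_bins)
    # assignment matrix: band z collects bins within +/- 0.5 Bark
    A <- outer(z_axis, zb, function(z, b) abs(z - b) <= 0.5) * 1
    .pcg_cache[[key]] <- list(A = A, e_tq = 10^(threshold_in_quiet(bark_to_hz(z_axis)) / 10))
  }
  cached <- .pcg_cache[[key]]
  E <- (cached$A %*% pow) / P0^2 # excitation re E0, bands x frames
  e_tq <- cached$e_tq
  n_prime <- 0.08 * (e_tq / 1)^0.23 *
    ((0.5 + 0.5 * E / e_tq)^0.23 - 1)
  n_prime[n_prime < 0] <- 0
  structure(
    list(
      bark_axis = z_axis,
      specific_loudness = n_prime,
      rate = rate,
      frame_sec = frame_sec
    ),
    class = "specific_loudness_pattern"
  )
}

# total loudness per frame, in (uncalibrated) model units
total_loudness_frames <- function(pattern) {
  dz <- pattern$bark_axis[2] - pattern$bark_axis[1]
  colSums(pattern$specific_loudness) * dz
}

# calibration constant: model loudness of the unit-defining anchor
# (1 kHz pure tone at 40 dB SPL == 1 sone), cached per model rate
loudness_anchor <- function(rate, frame_sec) {
  key <- paste0("anchor_", rate, "_", frame_sec)
  if (is.null(.pcg_cache[[key]])) {
    t <- seq(0, 1, by = 1 / rate)
    tone <- calibrated_signal(sin(2 * pi * 1000 * t), rate, 40)
    pat <- specific_loudness(tone, frame_sec)
    .pcg_cache[[key]] <- mean(total_loudness_frames(pat))
  }
  .pcg_cache[[key]]
}

#' Loudness in sone
#'
#' Time-mean of the Bark integral of the specific loudness pattern,
#' anchored so a 1 kHz tone at 40 dB SPL scores exactly 1 sone.
#'
#' @param pattern A `specific_loudness_pattern`.
#' @return Loudness in sone (non-negative scalar).
#' @export
loudness_feature <- function(pattern) {
  stopifnot(inherits(pattern, "specific_loudness_pattern"))
  mean(total_loudness_frames(pattern)) /
    loudness_anchor(pattern$rate, pattern$frame_sec)
}

#' Sharpness in acum
#'
#' Weighted first moment of the specific loudness pattern,
#' `S = 0.11 * sum(N'(z) g(z) z dz) / sum(N'(z) dz)`, with the DIN-45692
#' high-frequency emphasis `g(z) = 1` below 15.8 Bark and
#' `0.15 exp(0.42 (z - 15.8)) + 0.85` above. Frames are weighted by their
#' total loudness; a silent record scores 0.
#'
#' @param pattern A `specific_loudness_pattern`.
#' @return Sharpness in acum (non-negative scalar).
#' @export
sharpness_feature <- function(pattern) {
  stopifnot(inherits(pattern, "specific_loudness_pattern"))
  z <- pattern$bark_axis
  dz <- z[2] - z[1]
  g <- ifelse(z <= 15.8, 1, 0.15 * exp(0.42 * (z - 15.8)) + 0.85)
  np <- pattern$specific_loudness
  num <- colSums(np * g * z) * dz
  den <- colSums(np) * dz
  if (sum(den) <= 0) return(0)
  # loudness-weighted frame average of 0.11 * num/den
  0.11 * sum(num) / sum(den)
}
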