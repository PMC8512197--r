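# Roughness and fluctuation strength.
#
# Both sensations are driven by envelope modulation of the signal within
# critical bands: roughness by fast modulation (peaking near 70 Hz) and
# fluctuation strength by slow modulation (peaking near 4 Hz). The
# implementation decomposes the calibrated signal into overlapping
# 1-Bark-wide channels (0.5-Bark spacing), extracts each channel's Hilbert
# envelope exactly via frequency-domain band selection, computes the
# envelope modulation spectrum, and applies the model's modulation-rate
# weighting. Channel contributions (squared effective modulation depth)
# are integrated over the Bark axis, and each metric is anchored at its
# unit-defining stimulus: a 1 kHz tone at 60 dB SPL, 100% amplitude
# modulated at 70 Hz, has roughness 1 asper; the same tone modulated at
# 4 Hz has fluctuation strength 1 vacil. The Daniel-Weber cross-channel
# correlation factors are not modelled (documented simplification).

# roughness modulation-rate weighting, peak 1 at 70 Hz
roughness_weight <- function(f) {
  (2 * f * 70 / (f^2 + 70^2))^2
}

# fluctuation-strength weighting, peak 1 at 4 Hz (Fastl's 4-Hz bandpass law)
fluctuation_weight <- function(f) {
  2 / (f / 4 + 4 / f)
}

# Per-channel envelope modulation analysis shared by both metrics.
# Returns a list with, per channel: the mean envelope and the weighted
# effective modulation depths under each weighting. The leading and
# trailing 5% of each channel envelope are discarded before the modulation
# spectrum (the circular FFT band-selection wraps the record ends into an
# edge transient that is not signal modulation), and channels more than
# 26 dB below the strongest one are gated out (their envelopes carry only
# spectral leakage).
envelope_modulation <- function(sig, silence_floor = P0) {
  stopifnot(inherits(sig, "calibrated_signal"))
  x <- sig$samples
  n <- length(x)
  rate <- sig$rate
  dur <- n / rate
  X <- stats::fft(x)
  nyq_bark <- hz_to_bark(rate / 2)
  centers <- seq(0.5, nyq_bark - 0.5, by = 0.5)
  envelopes <- vector("list", length(centers))
  h0s <- numeric(length(centers))
  durs <- numeric(length(centers))
  for (i in seq_along(centers)) {
    f_lo <- bark_to_hz(centers[i] - 0.5)
    f_hi <- bark_to_hz(centers[i] + 0.5)
    k_lo <- max(1L, floor(f_lo * dur))
    k_hi <- min(n %/% 2L, ceiling(f_hi * dur))
    if (k_hi <= k_lo) next
    idx <- (k_lo:k_hi) + 1L # 1-based bins of positive frequencies
    nb <- length(idx)
    n2 <- stats::nextn(nb, c(2, 3, 5))
    env <- Mod(stats::fft(c(X[idx], rep(0i, n2 - nb)), inverse = TRUE)) *
      (2 / n) # complex-envelope magnitude, decimated to n2 samples
    trim <- max(1L, floor(0.05 * n2))
    env <- env[(trim + 1L):(n2 - trim)]
    envelopes[[i]] <- env
    h0s[i] <- mean(env)
    durs[i] <- dur * length(env) / n2
  }
  gate <- max(silence_floor, 0.05 * max(h0s))
  m_rough <- numeric(length(centers))
  m_fluct <- numeric(length(centers))
  for (i in seq_along(centers)) {
    if (is.null(envelopes[[i]]) || h0s[i] < gate) next
    env <- envelopes[[i]]
    n2 <- length(env)
    kmax <- n2 %/% 2L
    if (kmax < 1L) next
    H <- stats::fft(env - mean(env))
    fm <- (1:kmax) / durs[i]
    depth <- 2 * Mod(H[2:(kmax + 1L)]) / n2 / h0s[i]
    m_rough[i] <- min(1, sqrt(sum((roughness_weight(fm) * depth)^2)))
    m_fluct[i] <- min(1, sqrt(sum((fluctuation_weight(fm) * depth)^2)))
  }
  list(centers = centers, h0 = h0s, m_rough = m_rough, m_fluct = m_fluct)
}

modulation_metric_raw <- function(sig, which) {
  em <- envelope_modulation(sig)
  dz <- 0.5
  sum(em[[which]]^2) * dz
}

modulation_anchor <- function(rate, fmod, which) {
  key <- paste0("mod_anchor_", rate, "_", fmod, "_", which)
  if (is.null(.pcg_cache[[key]])) {
    dur <- max(2, ceiling(8 / fmod)) # resolve >= 8 modulation periods
    t <- seq(0, dur, by = 1 / rate)
    am <- (1 + cos(2 * pi * fmod * t)) * sin(2 * pi * 1000 * t)
    sig <- calibrated_signal(am, rate, 60)
    .pcg_cache[[key]] <- modulation_metric_raw(sig, which)
  }
  .pcg_cache[[key]]
}

#' Roughness in asper
#'
#' Envelope-modulation roughness with the 70-Hz-peaked modulation-rate
#' weighting, anchored so a fully modulated 1 kHz, 60 dB SPL tone at 70 Hz
#' scores 1 asper. Unmodulated stationary tones score ~0.
#'
#' @param sig A `calibrated_signal`.
#' @return Roughness in asper (non-negative scalar).
#' @export
roughness_feature <- function(sig) {
  modulation_metric_raw(sig, "m_rough") /
    modulation_anchor(sig$rate, 70, "m_rough")
}

#' Fluctuation strength in vacil
#'
#' Envelope-modulation fluctuation strength with the 4-Hz-peaked weighting,
#' anchored so a fully modulated 1 kHz, 60 dB SPL tone at 4 Hz scores
#' 1 vacil.
#'
#' @param sig A `calibrated_signal`.
#' @return Fluctuation strength in vacil (non-negative scalar).
#' @export
fluctuation_feature <- function(sig) {
  modulation_metric_raw(sig, "m_fluct") /
    modulation_anchor(sig$rate, 4, "m_fluct")
}

#' Psychoacoustic features of a preprocessed record
#'
#' Calibrates the record to a fixed SPL convention (unit RMS = 60 dB SPL),
#' upsamples to the model rate and computes the four psychoacoustic
#' features: roughness (asper), loudness (sone), sharpness (acum) and
#' fluctuation strength (vacil).
#'
#' @param rec A `pcg_record`.
#' @param reference_level dB SPL convention for unit-RMS input.
#' @param model_rate Psychoacoustic model rate in Hz.
#' @return Named list `roughness`, `loudness`, `sharpness`,
#'   `fluctuation_strength`.
#' @export
compute_acoustic_features <- function(rec, reference_level = 60,
                                      model_rate = 16000) {
  sig <- calibrate(rec, reference_level, model_rate)
  pattern <- specific_loudness(sig)
  list(
    roughness = roughness_feature(sig),
    loudness = loudness_feature(pattern),
    sharpness = sharpness_feature(pattern),
    fluctuation_strength = fluctuation_feature(sig)
  )
}
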