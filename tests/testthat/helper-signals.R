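# Shared fixtures: tones, noise records and quick canonical records are
# synthesised in code; no audio files ship with the package.

# a pure tone as a raw_record
tone_record <- function(freq, dur = 1, rate = 44100, amp = 1,
                        subject_id = "tone", label = "HC") {
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  raw_record(amp * sin(2 * pi * freq * t), rate, subject_id, label, "test")
}

# white-noise raw_record
noise_record <- function(dur = 1, rate = 44100, seed = 1,
                         subject_id = "noise", label = "HC") {
  set.seed(seed)
  raw_record(stats::rnorm(round(dur * rate)), rate, subject_id, label, "test")
}

# turn any waveform at 2 kHz into a canonical pcg_record (tiles/trims to
# 30 s, then z-scores through the public API)
as_pcg <- function(x, subject_id = "s1", label = "HC") {
  n <- 60000L
  x <- rep_len(as.numeric(x), n)
  zscore_record(raw_record(x, 2000, subject_id, label, "test"))
}

# multivariate-normal feature tibble with two shifted classes; `delta` = 0
# gives pure noise features. Fast stand-in for audio-derived features in
# CV-engine tests.
gaussian_features <- function(n_rhd, n_hc, delta = 3, p = 5, seed = 1) {
  set.seed(seed)
  n <- n_rhd + n_hc
  labels <- c(rep("RHD", n_rhd), rep("HC", n_hc))
  shift <- ifelse(labels == "RHD", delta, 0)
  mat <- matrix(stats::rnorm(n * p), n, p) + shift
  colnames(mat) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(
      subject_id = sprintf("%s-%02d", tolower(labels),
                           stats::ave(seq_len(n), labels, FUN = seq_along)),
      label = labels
    ),
    tibble::as_tibble(as.data.frame(mat))
  )
}
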