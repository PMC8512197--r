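#' Specification for one synthetic phonocardiogram
#'
#' The generator emulates the structure the screening pipeline assumes:
#' periodic S1/S2 transients (Gaussian-enveloped tone bursts near 60 and
#' 90 Hz), optional band-limited (150-400 Hz) murmur noise confined to the
#' systolic and/or diastolic interval for RHD-like records, cycle-length
#' jitter, and additive noise (white, or "babble" - slowly
#' amplitude-modulated speech-band noise imitating people talking).
#'
#' @param fs Sampling rate in Hz (>= 2000).
#' @param duration Record length in seconds (>= 30 so preprocessing accepts
#'   it; default 35).
#' @param heart_rate Beats per minute (default 70).
#' @param s1_freq,s2_freq Centre frequencies of the heart sounds (Hz).
#' @param s1_width,s2_width Gaussian envelope standard deviations (s).
#' @param murmur One of `"none"`, `"systolic"`, `"diastolic"`, `"both"`.
#'   Any murmur implies label RHD; `"none"` implies HC.
#' @param murmur_band Murmur noise band in Hz (default 150-400).
#' @param murmur_db Murmur-to-S1 energy ratio in dB (default -3).
#' @param noise_snr_db Record-level signal-to-noise ratio in dB (default 15).
#' @param noise_type `"babble"` (default) or `"white"`.
#' @param jitter Coefficient of variation of the cycle length (default 0.05).
#' @param systole Duration of the systolic interval in seconds.
#' @param seed RNG seed for this record.
#' @param subject_id,source Metadata carried into the record.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(fs = 2000, duration = 35, heart_rate = 70,
                       s1_freq = 60, s2_freq = 90,
                       s1_width = 0.02, s2_width = 0.015,
                       murmur = c("none", "systolic", "diastolic", "both"),
                       murmur_band = c(150, 400), murmur_db = -3,
                       noise_snr_db = 15, noise_type = c("babble", "white"),
                       jitter = 0.05, systole = 0.3, seed = 1,
                       subject_id = "synth-1", source = "synthetic") {
  murmur <- match.arg(murmur)
  noise_type <- match.arg(noise_type)
  stopifnot(fs >= 2000, duration >= 30)
  spec <- list(
    fs = fs, duration = duration, heart_rate = heart_rate,
    s1_freq = s1_freq, s2_freq = s2_freq,
    s1_width = s1_width, s2_width = s2_width,
    murmur = murmur, murmur_band = murmur_band, murmur_db = murmur_db,
    noise_snr_db = noise_snr_db, noise_type = noise_type,
    jitter = jitter, systole = systole, seed = seed,
    subject_id = subject_id, source = source,
    label = if (murmur == "none") "HC" else "RHD"
  )
  class(spec) <- "synth_spec"
  spec
}

# Gaussian-enveloped tone burst centred at time t0
tone_burst <- function(t, t0, freq, width) {
  exp(-0.5 * ((t - t0) / width)^2) * sin(2 * pi * freq * (t - t0))
}

# band-limited murmur noise confined to [t0, t1] with a Hann taper
murmur_noise <- function(t, fs, t0, t1, band) {
  x <- stats::rnorm(length(t))
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  win <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  ph <- (t[inside] - t0) / (t1 - t0)
  win[inside] <- 0.5 - 0.5 * cos(2 * pi * ph) # Hann gate
  x * win
}

#' Synthesize one heart cycle
#'
#' S1 at 10% and S2 at `10% + systole` of the (jittered) cycle; murmur
#' noise fills the systolic and/or diastolic interval with total energy
#' `murmur_db` dB relative to S1's energy. Uses the current RNG state when
#' called from [generate_record()]; called directly, it seeds from
#' `spec$seed` so two calls with the same spec are identical.
#'
#' @param spec A [synth_spec()].
#' @param reseed Seed from `spec$seed` first (default TRUE).
#' @return Numeric waveform of one cycle at `spec$fs`.
#' @export
synth_cycle <- function(spec, reseed = TRUE) {
  stopifnot(inherits(spec, "synth_spec"))
  if (reseed) set.seed(spec$seed)
  base_len <- 60 / spec$heart_rate
  cyc_len <- base_len * (1 + spec$jitter * stats::rnorm(1))
  cyc_len <- max(cyc_len, 0.9 * spec$systole + 0.2)
  t1 <- 0.1 * base_len # S1 centre
  t2 <- t1 + spec$systole # S2 centre
  if (t1 + 3 * spec$s1_width >= t2 - 3 * spec$s2_width ||
      t2 + 3 * spec$s2_width >= cyc_len) {
    stop("invalid configuration: S1/S2 envelopes overlap at this heart rate",
         call. = FALSE)
  }
  t <- seq(0, cyc_len, by = 1 / spec$fs)
  s1 <- tone_burst(t, t1, spec$s1_freq, spec$s1_width)
  s2 <- 0.7 * tone_burst(t, t2, spec$s2_freq, spec$s2_width)
  x <- s1 + s2
  e_s1 <- sum(s1^2)
  add_murmur <- function(x, t0, tend) {
    m <- murmur_noise(t, spec$fs, t0, tend, spec$murmur_band)
    e_m <- sum(m^2)
    if (e_m > 0) {
      x + m * sqrt(e_s1 * 10^(spec$murmur_db / 10) / e_m)
    } else {
      x
    }
  }
  gap <- 4 * spec$s2_width
  if (spec$murmur %in% c("systolic", "both")) {
    x <- add_murmur(x, t1 + 3 * spec$s1_width, t2 - 3 * spec$s2_width)
  }
  if (spec$murmur %in% c("diastolic", "both")) {
    x <- add_murmur(x, t2 + gap, cyc_len - 0.02)
  }
  x
}

#' Generate one labelled synthetic recording
#'
#' Concatenates jittered heart cycles to at least `spec$duration` seconds,
#' trims, and adds noise at `spec$noise_snr_db`. Deterministic given
#' `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return A [raw_record()] labelled from the murmur type.
#' @export
generate_record <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n_need <- as.integer(ceiling(spec$duration * spec$fs))
  chunks <- list()
  n_have <- 0L
  while (n_have < n_need) {
    cyc <- synth_cycle(spec, reseed = FALSE)
    chunks[[length(chunks) + 1L]] <- cyc
    n_have <- n_have + length(cyc)
  }
  x <- unlist(chunks)[seq_len(n_need)]
  p_sig <- mean(x^2)
  noise <- if (spec$noise_type == "white") {
    stats::rnorm(n_need)
  } else {
    babble_noise(n_need, spec$fs)
  }
  noise <- noise * sqrt(p_sig * 10^(-spec$noise_snr_db / 10) / mean(noise^2))
  raw_record(x + noise, spec$fs, spec$subject_id, spec$label, spec$source)
}

# speech-band (100-500 Hz) noise with slow random amplitude modulation,
# imitating people talking in the recording room
babble_noise <- function(n, fs) {
  x <- stats::rnorm(n)
  bf <- signal::butter(4, c(100, 500) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, x)
  n_seg <- max(4L, as.integer(n / fs * 4)) # ~4 Hz envelope variation
  env <- stats::approx(seq_len(n_seg), stats::runif(n_seg, 0.2, 1),
                       xout = seq(1, n_seg, length.out = n))$y
  x * env
}

#' Generate a labelled synthetic cohort
#'
#' Per-subject parameters are drawn from the study-condition ranges: heart
#' rate uniform 60-100 bpm, RHD murmur type systolic/diastolic/both with
#' probability 0.6/0.2/0.2, murmur level and noise SNR per difficulty
#' preset. The `"separable"` preset (murmur -6..0 dB re S1, SNR 12-18 dB)
#' gives clearly audible murmurs; `"hard"` (murmur -18..-10 dB, SNR -2..2
#' dB) buries them in noise.
#'
#' @param n_rhd,n_hc Cohort sizes (defaults 124 and 127).
#' @param seed Master seed.
#' @param preset `"separable"` (default) or `"hard"`.
#' @param duration Record duration in seconds (default 35).
#' @param fs Sampling rate (default 2000).
#' @return Manifest tibble: `subject_id`, `label`, `source`, and `record`
#'   list-column of [raw_record()] objects.
#' @export
generate_dataset <- function(n_rhd = 124, n_hc = 127, seed = 1,
                             preset = c("separable", "hard"),
                             duration = 35, fs = 2000) {
  preset <- match.arg(preset)
  stopifnot(n_rhd >= 1, n_hc >= 1)
  set.seed(seed)
  n <- n_rhd + n_hc
  labels <- c(rep("RHD", n_rhd), rep("HC", n_hc))
  hr <- stats::runif(n, 60, 100)
  murmur_types <- c(sample(c("systolic", "diastolic", "both"), n_rhd,
                           replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                    rep("none", n_hc))
  if (preset == "separable") {
    mdb <- stats::runif(n, -6, 0)
    snr <- stats::runif(n, 12, 18)
  } else {
    mdb <- stats::runif(n, -18, -10)
    snr <- stats::runif(n, -2, 2)
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("%s-%03d", tolower(labels), stats::ave(
    seq_len(n), labels, FUN = seq_along))
  records <- lapply(seq_len(n), function(i) {
    generate_record(synth_spec(
      fs = fs, duration = duration, heart_rate = hr[i],
      murmur = murmur_types[i], murmur_db = mdb[i],
      noise_snr_db = snr[i], seed = seeds[i],
      subject_id = ids[i]
    ))
  })
  tibble::tibble(
    subject_id = ids,
    label = labels,
    source = "synthetic",
    record = records
  )
}

#' Write a generated dataset as WAV files plus manifest
#'
#' @param data Manifest tibble from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(nrow(data))
  for (i in seq_len(nrow(data))) {
    rec <- data$record[[i]]
    paths[i] <- paste0(data$subject_id[i], ".wav")
    write_wav(rec$samples, rec$rate, file.path(dir, paths[i]))
  }
  manifest <- data.frame(
    subject_id = data$subject_id, label = data$label,
    source = data$source, path = paths
  )
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
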