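rms_of <- function(x) sqrt(mean(x^2))

test_that("bandpass keeps in-band tones and rejects out-of-band tones", {
  in_band <- bandpass_filter(tone_record(500, dur = 2))
  expect_equal(rms_of(in_band$samples), rms_of(tone_record(500, dur = 2)$samples),
               tolerance = 0.05)
  low <- bandpass_filter(tone_record(5, dur = 2))
  expect_lt(rms_of(low$samples), 0.1 * rms_of(tone_record(5, dur = 2)$samples))
  expect_error(bandpass_filter(tone_record(100, rate = 2000), high = 1000),
               "Nyquist")
})

test_that("out-of-band rejection exceeds 40 dB on a periodogram estimate", {
  rec <- bandpass_filter(noise_record(dur = 4, seed = 2))
  # independent PSD oracle: plain periodogram with coarse smoothing
  sp <- stats::spec.pgram(stats::ts(rec$samples, frequency = rec$rate),
                         spans = 31, plot = FALSE, taper = 0)
  p_at <- function(f) sp$spec[which.min(abs(sp$freq - f))]
  expect_lt(10 * log10(p_at(2000) / p_at(500)), -40)
})

test_that("zero-phase filtering leaves in-band timing untouched", {
  # a burst's energy centroid must not move (no group delay)
  t <- seq(0, 2 - 1 / 44100, by = 1 / 44100)
  burst <- exp(-0.5 * ((t - 1) / 0.01)^2) * sin(2 * pi * 300 * (t - 1))
  rec <- raw_record(burst, 44100, "b", "HC", "test")
  out <- bandpass_filter(rec)
  cen <- function(x) sum(seq_along(x) * x^2) / sum(x^2)
  expect_equal(cen(out$samples), cen(burst), tolerance = 20) # < 0.5 ms
})

test_that("resampling preserves length arithmetic and tone frequency", {
  rec <- tone_record(100, dur = 60)
  out <- resample_to(rec, 2000)
  expect_equal(length(out$samples), 120000)
  expect_equal(out$rate, 2000)
  sp <- stats::spec.pgram(stats::ts(out$samples, frequency = 2000),
                         plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)], 100, tolerance = 2)
  expect_error(resample_to(tone_record(100, rate = 2000), 4000), "upsampl")
})

test_that("a chirp's spectrogram ridge survives resampling", {
  rate <- 44100
  t <- seq(0, 10 - 1 / rate, by = 1 / rate)
  f_inst <- 20 + (900 - 20) * t / 10
  chirp <- sin(2 * pi * cumsum(f_inst) / rate)
  rec <- raw_record(chirp, rate, "c", "HC", "test")
  out <- resample_to(bandpass_filter(rec), 2000)
  ridge <- function(x, fs) {
    n <- 512
    hops <- seq(1, length(x) - n, by = n)
    vapply(hops, function(h) {
      sp <- Mod(stats::fft(x[h:(h + n - 1)] * signal::hanning(n)))[1:(n / 2)]
      (which.max(sp) - 1) * fs / n
    }, numeric(1))
  }
  r_out <- ridge(out$samples, 2000)
  # expected instantaneous frequency at the same time points
  mid_t <- (seq(1, length(out$samples) - 512, by = 512) + 256) / 2000
  f_exp <- 20 + (900 - 20) * mid_t / 10
  expect_true(all(abs(r_out - f_exp) < 2000 / 512 + 1e-9))
})

test_that("segment extraction enforces the 30-s inclusion rule", {
  r47 <- noise_record(dur = 47, rate = 2000, seed = 3)
  out <- extract_segment(r47)
  expect_equal(length(out$samples), 60000)
  expect_error(extract_segment(noise_record(dur = 29, rate = 2000)),
               "rejected")
  r30 <- noise_record(dur = 30, rate = 2000, seed = 4)
  out30 <- extract_segment(r30)
  expect_identical(out30$samples, r30$samples[1:60000])
})

test_that("z-scoring normalises, rejects constants, and is idempotent", {
  rec <- noise_record(dur = 30, rate = 2000, seed = 5)
  z <- zscore_record(rec)
  expect_lt(abs(mean(z$samples)), 1e-8)
  expect_lt(abs(sd(z$samples) - 1), 1e-8)
  expect_error(
    zscore_record(raw_record(rep(1, 60000), 2000, "c", "HC", "t")),
    "degenerate"
  )
  z2 <- zscore_record(raw_record(z$samples, 2000, "s", "HC", "t"))
  expect_equal(z2$samples, z$samples, tolerance = 1e-12)
})

test_that("the full preprocessing chain is deterministic and canonical", {
  rec <- generate_record(synth_spec(fs = 4000, seed = 11, duration = 60,
                                    subject_id = "p1"))
  out1 <- preprocess_record(rec)
  out2 <- preprocess_record(rec)
  expect_equal(length(out1$samples), 60000)
  expect_equal(out1$rate, 2000)
  expect_identical(out1$samples, out2$samples)
  short <- raw_record(rnorm(20 * 44100), 44100, "s", "HC", "t")
  expect_error(preprocess_record(short), "rejected")
})

test_that("records at 2 kHz preprocess cleanly despite the Nyquist band edge", {
  rec <- generate_record(synth_spec(seed = 12, subject_id = "p2"))
  expect_equal(rec$rate, 2000)
  out <- preprocess_record(rec)
  expect_equal(length(out$samples), 60000)
})

test_that("in-band energy ordering survives preprocessing (pre z-score)", {
  loud <- bandpass_filter(tone_record(300, dur = 2, amp = 2))
  quiet <- bandpass_filter(tone_record(300, dur = 2, amp = 1))
  expect_gt(rms_of(loud$samples), rms_of(quiet$samples))
})
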