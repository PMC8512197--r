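band_energy <- function(x, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  sum(signal::filtfilt(bf, x)^2)
}

test_that("murmur-free cycles keep the systolic band 10 dB under S1", {
  spec <- synth_spec(murmur = "none", seed = 71)
  cyc <- synth_cycle(spec)
  e_band <- band_energy(cyc, spec$fs, c(150, 400))
  t <- seq(0, (length(cyc) - 1) / spec$fs, by = 1 / spec$fs)
  s1 <- exp(-0.5 * ((t - 0.1 * 60 / spec$heart_rate) / spec$s1_width)^2) *
    sin(2 * pi * spec$s1_freq * (t - 0.1 * 60 / spec$heart_rate))
  e_s1 <- sum(s1^2)
  expect_lt(10 * log10(e_band / e_s1), -10)
})

test_that("a 0 dB systolic murmur lands within 3 dB of S1 energy", {
  spec <- synth_spec(murmur = "systolic", murmur_db = 0, seed = 72,
                     noise_snr_db = 60)
  cyc <- synth_cycle(spec)
  t <- seq(0, (length(cyc) - 1) / spec$fs, by = 1 / spec$fs)
  t1 <- 0.1 * 60 / spec$heart_rate
  s1 <- exp(-0.5 * ((t - t1) / spec$s1_width)^2) *
    sin(2 * pi * spec$s1_freq * (t - t1))
  e_s1 <- sum(s1^2)
  # isolate the murmur window between the heart sounds
  sys <- t > t1 + 3 * spec$s1_width & t < t1 + spec$systole - 3 * spec$s2_width
  e_band <- band_energy(cyc[sys], spec$fs, c(150, 400))
  expect_lt(abs(10 * log10(e_band / e_s1)), 3)
})

test_that("generation is deterministic per seed", {
  expect_identical(synth_cycle(synth_spec(seed = 73)),
                   synth_cycle(synth_spec(seed = 73)))
  a <- generate_record(synth_spec(seed = 74, murmur = "both"))
  b <- generate_record(synth_spec(seed = 74, murmur = "both"))
  expect_identical(a$samples, b$samples)
  expect_equal(a$label, "RHD")
})

test_that("excessive heart rates trip the envelope-overlap guard", {
  expect_error(synth_cycle(synth_spec(heart_rate = 400, systole = 0.1,
                                      s1_width = 0.03, s2_width = 0.03)),
               "overlap")
})

test_that("default specs survive the full preprocessing contract", {
  rec <- generate_record(synth_spec(seed = 75))
  p <- preprocess_record(rec)
  expect_equal(length(p$samples), 60000)
  expect_lt(abs(mean(p$samples)), 1e-8)
})

test_that("cohort generation matches the requested composition", {
  data <- generate_dataset(n_rhd = 5, n_hc = 7, seed = 76, duration = 30)
  expect_equal(nrow(data), 12)
  expect_equal(sum(data$label == "RHD"), 5)
  expect_equal(anyDuplicated(data$subject_id), 0)
  again <- generate_dataset(n_rhd = 5, n_hc = 7, seed = 76, duration = 30)
  expect_identical(data$subject_id, again$subject_id)
  expect_identical(data$record[[3]]$samples, again$record[[3]]$samples)
})

test_that("murmurs raise systolic-band energy consistently across seeds", {
  diffs <- vapply(1:20, function(seed) {
    rhd <- generate_record(synth_spec(murmur = "systolic", seed = seed,
                                      subject_id = "r"))
    hc <- generate_record(synth_spec(murmur = "none", seed = seed + 1000,
                                     subject_id = "h"))
    log10(band_energy(rhd$samples, 2000, c(150, 400)) /
            band_energy(hc$samples, 2000, c(150, 400)))
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("murmur strength separates spectral features across seeds", {
  entropies <- vapply(1:10, function(seed) {
    rhd <- preprocess_record(generate_record(
      synth_spec(murmur = "systolic", seed = seed, subject_id = "r")))
    hc <- preprocess_record(generate_record(
      synth_spec(murmur = "none", seed = seed + 500, subject_id = "h")))
    fr <- compute_frequency_features(estimate_psd(rhd))
    fh <- compute_frequency_features(estimate_psd(hc))
    fr$spectral_entropy - fh$spectral_entropy
  }, numeric(1))
  expect_true(abs(mean(entropies)) > 2 * sd(entropies) / sqrt(10))
})

test_that("feature extraction stays finite at -20 dB SNR", {
  rec <- generate_record(synth_spec(murmur = "both", noise_snr_db = -20,
                                    seed = 77))
  fv <- extract_features_record(preprocess_record(rec))
  expect_true(all(is.finite(fv)))
})
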