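#' Zero-phase Butterworth bandpass filter
#'
#' Applies a 4th-order Butterworth bandpass (default 20 Hz - 1 kHz, the
#' murmur-relevant band) forward and backward, so in-band content suffers no
#' phase distortion and murmur timing is preserved. The same filter acts as
#' the antialiasing stage before resampling to 2 kHz.
#'
#' @param rec A [raw_record()].
#' @param low Lower band edge in Hz.
#' @param high Upper band edge in Hz; must be below the Nyquist frequency.
#' @param order Butterworth order (applied twice via filtfilt).
#' @return A [raw_record()] with filtered samples, same length and rate.
#' @export
bandpass_filter <- function(rec, low = 20, high = 1000, order = 4) {
  stopifnot(inherits(rec, "raw_record"))
  nyq <- rec$rate / 2
  if (!(low < high)) {
    stop("bandpass_filter: need low < high", call. = FALSE)
  }
  if (high >= nyq) {
    stop(sprintf(
      "bandpass_filter: upper edge %g Hz must be below Nyquist (%g Hz)",
      high, nyq
    ), call. = FALSE)
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtered <- signal::filtfilt(bf, rec$samples)
  raw_record(filtered, rec$rate, rec$subject_id, rec$label, rec$source)
}

#' Resample a recording to a target rate
#'
#' Polyphase rational resampling. The caller is responsible for bandlimiting
#' first (the preprocessing chain runs [bandpass_filter()] before this).
#'
#' @param rec A [raw_record()].
#' @param target_rate Target sampling rate in Hz (default 2000).
#' @return A [raw_record()] at `target_rate` with
#'   `round(n * target_rate / rate)` samples.
#' @export
resample_to <- function(rec, target_rate = 2000) {
  stopifnot(inherits(rec, "raw_record"))
  if (target_rate > rec$rate) {
    stop("resample_to: upsampling is not part of the preprocessing chain",
         call. = FALSE)
  }
  if (target_rate == rec$rate) {
    return(rec)
  }
  frac <- ratio_integers(target_rate, rec$rate)
  out <- signal::resample(rec$samples, frac$p, frac$q)
  n_target <- round(length(rec$samples) * target_rate / rec$rate)
  out <- fix_length(out, n_target)
  raw_record(out, target_rate, rec$subject_id, rec$label, rec$source)
}

# smallest integer ratio p/q equal to a/b
ratio_integers <- function(a, b) {
  g <- gcd_int(round(a), round(b))
  list(p = round(a) / g, q = round(b) / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

fix_length <- function(x, n) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(0, n - length(x)))
}

#' Extract a single fixed-duration segment
#'
#' Takes one `duration`-second window (by default the first 30 s, the
#' deterministic choice) from a recording. Records shorter than `duration`
#' are rejected, mirroring the inclusion rule that a usable record must be
#' at least 30 s long.
#'
#' @param rec A [raw_record()].
#' @param duration Segment length in seconds (default 30).
#' @param offset Start of the window in seconds (default 0).
#' @return A [raw_record()] with exactly `duration * rate` samples.
#' @export
extract_segment <- function(rec, duration = 30, offset = 0) {
  stopifnot(inherits(rec, "raw_record"))
  n_need <- as.integer(round(duration * rec$rate))
  i0 <- as.integer(round(offset * rec$rate))
  if (length(rec$samples) < i0 + n_need) {
    stop(sprintf(
      "record rejected: %.1f s available, %g s required (subject %s)",
      (length(rec$samples) - i0) / rec$rate, duration, rec$subject_id
    ), call. = FALSE)
  }
  raw_record(rec$samples[(i0 + 1):(i0 + n_need)], rec$rate,
             rec$subject_id, rec$label, rec$source)
}

#' Z-score a recording into canonical form
#'
#' Normalises to zero mean and unit standard deviation, producing the
#' canonical `pcg_record` on which all features are computed. Constant
#' signals are degenerate and rejected.
#'
#' @param rec A [raw_record()] of exactly 30 s at 2 kHz.
#' @return A `pcg_record`.
#' @export
zscore_record <- function(rec) {
  stopifnot(inherits(rec, "raw_record"))
  sdev <- stats::sd(rec$samples)
  if (!is.finite(sdev) || sdev == 0) {
    stop("degenerate signal: zero variance, cannot z-score", call. = FALSE)
  }
  z <- (rec$samples - mean(rec$samples)) / sdev
  # one exact re-centering pass so the pcg_record invariants hold to 1e-8
  z <- (z - mean(z)) / stats::sd(z)
  new_pcg_record(z, rec$subject_id, rec$label, rec$source, rate = rec$rate)
}

#' Preprocess a raw recording into canonical form
#'
#' The full deterministic chain: bandpass 20 Hz-1 kHz (zero phase), resample
#' to 2 kHz, keep the first 30 s, z-score. For inputs whose rate puts the
#' 1 kHz band edge at or above Nyquist (e.g. recordings already at 2 kHz),
#' the upper edge is clamped to 0.49 x rate so the filter stays well defined.
#'
#' @param rec A [raw_record()].
#' @param low,high Band edges in Hz.
#' @param target_rate Canonical rate (2000 Hz).
#' @param duration Canonical duration in seconds (30).
#' @param offset Segment start in seconds (default 0).
#' @return A `pcg_record`: 60 000 samples, 2 kHz, zero mean, unit sd.
#' @export
preprocess_record <- function(rec, low = 20, high = 1000,
                              target_rate = 2000, duration = 30, offset = 0) {
  stopifnot(inherits(rec, "raw_record"))
  eff_high <- if (high >= 0.5 * rec$rate) 0.49 * rec$rate else high
  rec |>
    bandpass_filter(low = low, high = eff_high) |>
    resample_to(target_rate) |>
    extract_segment(duration = duration, offset = offset) |>
    zscore_record()
}

#' Preprocess every record of a manifest tibble
#'
#' @param data A tibble with columns `subject_id`, `label`, `source` and a
#'   `record` list-column of [raw_record()] objects (as returned by
#'   [read_manifest()] or [generate_dataset()]).
#' @param ... Passed to [preprocess_record()].
#' @return The input tibble with `record` replaced by preprocessed
#'   `pcg_record` objects; records that fail preprocessing (e.g. shorter
#'   than 30 s) are dropped with a warning naming the subject.
#' @export
preprocess_dataset <- function(data, ...) {
  keep <- rep(TRUE, nrow(data))
  out <- vector("list", nrow(data))
  for (i in seq_len(nrow(data))) {
    res <- tryCatch(preprocess_record(data$record[[i]], ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("subject %s skipped: %s", data$subject_id[[i]],
                      conditionMessage(res)), call. = FALSE)
      keep[i] <- FALSE
    } else {
      out[[i]] <- res
    }
  }
  res <- data[keep, , drop = FALSE]
  res$record <- out[keep]
  res
}
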