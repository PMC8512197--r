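#' Construct a raw heart-sound recording
#'
#' A `raw_record` is the entry point of the pipeline: a single-channel
#' amplitude trace with its sampling rate, a subject identifier and a binary
#' screening label. Exactly one record per subject enters any experiment.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), all finite.
#' @param rate Sampling rate in Hz; must be at least 2000.
#' @param subject_id Opaque subject identifier (string).
#' @param label Either `"RHD"` (case) or `"HC"` (healthy control).
#' @param source Free-text provenance tag, e.g. `"synthetic"`.
#'
#' @return An object of class `raw_record`.
#' @export
raw_record <- function(samples, rate, subject_id, label, source = "unknown") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("raw_record: `samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("raw_record: all samples must be finite", call. = FALSE)
  }
  rate <- as.numeric(rate)
  if (length(rate) != 1L || !is.finite(rate) || rate < 2000) {
    stop("raw_record: `rate` must be a single value >= 2000 Hz", call. = FALSE)
  }
  label <- match.arg(label, c("RHD", "HC"))
  structure(
    list(
      samples = samples,
      rate = rate,
      subject_id = as.character(subject_id),
      label = label,
      source = as.character(source)
    ),
    class = "raw_record"
  )
}

#' @export
print.raw_record <- function(x, ...) {
  cat(sprintf(
    "<raw_record> subject %s [%s] %.1f s @ %g Hz (%s)\n",
    x$subject_id, x$label, length(x$samples) / x$rate, x$rate, x$source
  ))
  invisible(x)
}

# Canonical preprocessed form: 30 s at 2 kHz, zero mean, unit standard
# deviation. Constructed only by the preprocessing chain (or tests).
new_pcg_record <- function(samples, subject_id, label, source = "unknown",
                           rate = 2000, duration = 30) {
  n_expected <- as.integer(round(rate * duration))
  if (length(samples) != n_expected) {
    stop(sprintf(
      "pcg_record: expected exactly %d samples, got %d",
      n_expected, length(samples)
    ), call. = FALSE)
  }
  mu <- mean(samples)
  sdev <- stats::sd(samples)
  if (abs(mu) > 1e-8 || abs(sdev - 1) > 1e-8) {
    stop("pcg_record: samples must be z-scored (mean 0, sd 1)", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      rate = rate,
      duration = duration,
      subject_id = as.character(subject_id),
      label = label,
      source = as.character(source)
    ),
    class = "pcg_record"
  )
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf(
    "<pcg_record> subject %s [%s] %g s @ %g Hz, z-scored\n",
    x$subject_id, x$label, x$duration, x$rate
  ))
  invisible(x)
}

is_pcg_record <- function(x) inherits(x, "pcg_record")

stopifnot_pcg <- function(rec) {
  if (!is_pcg_record(rec)) {
    stop("expected a `pcg_record` (run preprocess_record() first)", call. = FALSE)
  }
  invisible(rec)
}
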