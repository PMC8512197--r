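#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for the formats produced by electronic
#' stethoscopes and by [write_wav()]: integer PCM (16/24/32-bit) and IEEE
#' float32, single channel. Integer PCM is rescaled to `[-1, 1]`; absolute
#' scale is irrelevant downstream because every record is z-scored.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]` for PCM) and
#'   `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little") # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      u16 <- function(i) sum(as.integer(raw_fmt[i:(i + 1)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(raw_fmt[i:(i + 3)]) * 256^(0:3))
      fmt <- list(
        audio_format = u16(1), channels = u16(3),
        rate = u32(5), bits = u16(15)
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      samples <- read_wav_data(con, sz, fmt)
    } else {
      readBin(con, "raw", sz + (sz %% 2L)) # skip unknown chunk (word aligned)
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("WAV file has no data chunk: ", path, call. = FALSE)
  if (fmt$channels != 1L) {
    stop(sprintf("stereo/multichannel WAV not supported (%d channels): %s",
                 fmt$channels, path), call. = FALSE)
  }
  list(samples = samples, rate = fmt$rate)
}

read_wav_data <- function(con, sz, fmt) {
  bits <- fmt$bits
  if (fmt$audio_format == 3L) { # IEEE float
    if (bits != 32L) stop("only 32-bit float WAV supported", call. = FALSE)
    return(readBin(con, "double", sz / 4L, size = 4L, endian = "little"))
  }
  if (fmt$audio_format != 1L) {
    stop("unsupported WAV audio format code: ", fmt$audio_format, call. = FALSE)
  }
  if (bits == 16L) {
    x <- readBin(con, "integer", sz / 2L, size = 2L, signed = TRUE,
                 endian = "little")
    x / 32768
  } else if (bits == 24L) {
    raw3 <- readBin(con, "raw", sz)
    n <- length(raw3) %/% 3L
    b <- matrix(as.integer(raw3[seq_len(n * 3L)]), nrow = 3L)
    v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
    v <- ifelse(v >= 8388608, v - 16777216, v)
    v / 8388608
  } else if (bits == 32L) {
    x <- readBin(con, "integer", sz / 4L, size = 4L, endian = "little")
    x / 2147483648
  } else {
    stop("unsupported PCM bit depth: ", bits, call. = FALSE)
  }
}

#' Write a mono WAV file
#'
#' Writes float32 WAV (the canonical serialization of preprocessed records)
#' or 16-bit PCM.
#'
#' @param samples Numeric amplitude vector.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @param bits 32 for IEEE float32 (default) or 16 for integer PCM.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path, bits = 32) {
  if (!bits %in% c(16, 32)) stop("bits must be 16 or 32", call. = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- bits / 8L
  data_sz <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_sz), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(fmt_code, con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little") # mono
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4L, endian = "little")
  if (bits == 32) {
    writeBin(samples, con, size = 4L, endian = "little")
  } else {
    x <- as.integer(pmax(pmin(round(samples * 32767), 32767), -32768))
    writeBin(x, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read a dataset manifest and its WAV files
#'
#' The manifest is a CSV with header `subject_id,label,source,path`; paths
#' are resolved relative to the manifest's directory unless absolute.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A tibble with columns `subject_id`, `label`, `source` and a
#'   list-column `record` of [raw_record()] objects.
#' @export
read_manifest <- function(manifest_path) {
  tab <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("subject_id", "label", "source", "path")
  if (!all(required %in% names(tab))) {
    stop("manifest must have columns: ", paste(required, collapse = ","),
         call. = FALSE)
  }
  if (anyDuplicated(tab$subject_id)) {
    stop("manifest violates the one-record-per-subject rule", call. = FALSE)
  }
  base <- dirname(manifest_path)
  records <- purrr::pmap(tab, function(subject_id, label, source, path, ...) {
    full <- if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base, path)
    wav <- read_wav(full)
    raw_record(wav$samples, wav$rate, subject_id, label, source)
  })
  tibble::tibble(
    subject_id = as.character(tab$subject_id),
    label = tab$label,
    source = tab$source,
    record = records
  )
}
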