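#' Canonical feature names
#'
#' The 31 features in canonical order: acoustic (4), frequency (5),
#' time (9), perceptual (13). Column order is part of the feature-table
#' format contract.
#'
#' @param groups Character subset of
#'   `c("acoustic", "frequency", "time", "perceptual")` to include.
#' @return Character vector of feature names.
#' @export
feature_names <- function(groups = c("acoustic", "frequency", "time",
                                     "perceptual")) {
  groups <- match.arg(groups, several.ok = TRUE,
                      choices = c("acoustic", "frequency", "time", "perceptual"))
  all <- list(
    acoustic = c("roughness", "loudness", "sharpness", "fluctuation_strength"),
    frequency = c("spectral_entropy", "dominant_frequency_value",
                  "dominant_frequency_magnitude", "dominant_frequency_ratio",
                  "bandwidth"),
    time = c("median", "mean_absolute_deviation", "q1", "q3", "iqr",
             "skewness", "kurtosis", "shannon_energy", "zero_crossing_rate"),
    perceptual = paste0("mfcc", 1:13)
  )
  unlist(all[c("acoustic", "frequency", "time", "perceptual")[
    c("acoustic", "frequency", "time", "perceptual") %in% groups]],
    use.names = FALSE)
}

#' Assemble the canonical 31-value feature vector
#'
#' Concatenates the four feature groups (computed from the same record) in
#' canonical order and validates finiteness.
#'
#' @param acoustic,frequency,time,perceptual Named lists as returned by the
#'   group-level feature functions.
#' @return A named numeric vector of length 31.
#' @export
assemble_feature_vector <- function(acoustic, frequency, time, perceptual) {
  v <- unlist(c(acoustic, frequency, time, perceptual))
  expected <- feature_names()
  if (length(v) != length(expected) || !identical(names(v), expected)) {
    stop("feature groups do not form the canonical 31-feature layout",
         call. = FALSE)
  }
  bad <- !is.finite(v)
  if (any(bad)) {
    stop("non-finite feature value(s): ",
         paste(names(v)[bad], collapse = ", "), call. = FALSE)
  }
  v
}

#' Extract the full feature vector from one preprocessed record
#'
#' @param rec A `pcg_record`.
#' @param groups Feature groups to compute (default all four; dropping
#'   `"acoustic"` yields the 27-feature ablation set).
#' @param mfcc MFCC configuration, an [mfcc_config()].
#' @param reference_level,model_rate Psychoacoustic calibration settings.
#' @return A named numeric vector in canonical order.
#' @export
extract_features_record <- function(rec,
                                    groups = c("acoustic", "frequency",
                                               "time", "perceptual"),
                                    mfcc = mfcc_config(),
                                    reference_level = 60,
                                    model_rate = 16000) {
  stopifnot_pcg(rec)
  if (setequal(groups, c("acoustic", "frequency", "time", "perceptual"))) {
    v <- assemble_feature_vector(
      compute_acoustic_features(rec, reference_level, model_rate),
      compute_frequency_features(estimate_psd(rec)),
      compute_time_features(rec),
      mfcc_features(rec, mfcc)
    )
    return(v)
  }
  parts <- list()
  if ("acoustic" %in% groups) {
    parts <- c(parts, compute_acoustic_features(rec, reference_level, model_rate))
  }
  if ("frequency" %in% groups) {
    parts <- c(parts, compute_frequency_features(estimate_psd(rec)))
  }
  if ("time" %in% groups) parts <- c(parts, compute_time_features(rec))
  if ("perceptual" %in% groups) parts <- c(parts, mfcc_features(rec, mfcc))
  v <- unlist(parts)
  bad <- !is.finite(v)
  if (any(bad)) {
    stop("non-finite feature value(s): ",
         paste(names(v)[bad], collapse = ", "), call. = FALSE)
  }
  v[feature_names(groups)]
}

#' Extract features for every record of a dataset tibble
#'
#' The data-frame-first entry point of the feature stage: takes a manifest
#' tibble whose `record` column holds raw or preprocessed records, runs
#' preprocessing where needed, and returns one row per subject with the
#' canonical feature columns.
#'
#' @param data Tibble with `subject_id`, `label`, `source` and a `record`
#'   list-column ([raw_record()] or `pcg_record` objects).
#' @param groups Feature groups to compute.
#' @param ... Passed to [extract_features_record()].
#' @return A tibble: `subject_id`, `label`, then the feature columns in
#'   canonical order.
#' @export
extract_features <- function(data, groups = c("acoustic", "frequency",
                                              "time", "perceptual"), ...) {
  needs_prep <- !purrr::map_lgl(data$record, is_pcg_record)
  if (any(needs_prep)) {
    data <- preprocess_dataset(data)
  }
  feats <- purrr::map(data$record, extract_features_record,
                      groups = groups, ...)
  mat <- do.call(rbind, feats)
  dplyr::bind_cols(
    tibble::tibble(subject_id = data$subject_id, label = data$label),
    tibble::as_tibble(as.data.frame(mat))
  )
}

#' Write / read a feature table CSV
#'
#' One row per subject; columns `subject_id`, `label`, then the canonical
#' feature names. Exact column order is part of the format contract.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path` (write) or the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("subject_id", "label") %in% names(tab))) {
    stop("feature table must start with subject_id,label columns",
         call. = FALSE)
  }
  tibble::as_tibble(tab)
}
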