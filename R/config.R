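#' Validate an experiment run configuration
#'
#' A run configuration drives [cmd_evaluate()]: protocol, prevalence,
#' repeats, seed, hyperparameter grid and feature-group toggles. Unknown
#' keys are rejected, and configuration errors surface before any
#' computation.
#'
#' @param config A named list (e.g. from [read_run_config()]).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  known <- c("protocol", "prevalence", "repeats", "seed", "k",
             "grid", "feature_groups", "mfcc", "reference_level",
             "model_rate")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$protocol) ||
      !config$protocol %in% c("stratified", "imbalanced")) {
    stop("config: `protocol` must be 'stratified' or 'imbalanced'",
         call. = FALSE)
  }
  if (config$protocol == "imbalanced") {
    if (is.null(config$prevalence)) {
      stop("config: imbalanced protocol requires `prevalence`", call. = FALSE)
    }
    hc_count_for_prevalence(config$prevalence) # range check
  } else if (!is.null(config$prevalence)) {
    stop("config: `prevalence` conflicts with the stratified protocol",
         call. = FALSE)
  }
  config$repeats <- config$repeats %||% 5
  config$seed <- config$seed %||% 1
  config$k <- config$k %||% 10
  if (is.null(config$grid)) {
    config$grid <- default_grid()
  } else {
    if (!all(c("C", "gamma") %in% names(config$grid))) {
      stop("config: `grid` needs numeric vectors C and gamma", call. = FALSE)
    }
    config$grid <- list(C = as.numeric(config$grid$C),
                        gamma = as.numeric(config$grid$gamma))
  }
  config$feature_groups <- config$feature_groups %||%
    c("acoustic", "frequency", "time", "perceptual")
  bad <- setdiff(config$feature_groups,
                 c("acoustic", "frequency", "time", "perceptual"))
  if (length(bad) > 0) {
    stop("config: unknown feature group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  config
}

#' Read a YAML run configuration
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
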