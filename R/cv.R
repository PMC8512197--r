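#' Run a nested cross-validation experiment
#'
#' For every outer fold of every repeat: select hyperparameters by
#' [grid_search()] on the fold's inner folds (pooled inner-test f1), refit
#' on the full outer training partition with the winning pair, and predict
#' the outer test set. Within each repeat all outer-fold predictions are
#' pooled into one metric set; the report carries the per-repeat metrics,
#' their mean and standard deviation, and the hyperparameters selected per
#' fold. Standardization statistics are always re-fit on the current
#' training partition only, and the plan is leakage-audited before any
#' model is fit.
#'
#' @param plan A `fold_plan` from [stratified_fold_plan()] or
#'   [imbalanced_fold_plan()].
#' @param features Feature tibble from [extract_features()] (columns
#'   `subject_id`, `label`, then features).
#' @param grid Hyperparameter grid (default the full 5 x 5 grid).
#' @return A `cv_report`.
#' @export
run_nested_cv <- function(plan, features, grid = default_grid()) {
  stopifnot(inherits(plan, "fold_plan"))
  audit_fold_plan(plan)
  feat_cols <- setdiff(names(features), c("subject_id", "label"))
  X <- as.matrix(features[, feat_cols])
  rownames(X) <- features$subject_id
  y <- stats::setNames(as.character(features$label), features$subject_id)

  plan_ids <- unique(unlist(lapply(plan$repeats, function(r) {
    unlist(lapply(r$outer_folds, function(f) c(f$train, f$test)))
  })))
  missing <- setdiff(plan_ids, features$subject_id)
  if (length(missing) > 0) {
    stop("plan references subjects absent from the feature table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }

  idx_of <- function(ids) match(ids, features$subject_id)
  per_repeat <- list()
  hp_rows <- list()
  for (r in seq_along(plan$repeats)) {
    rep_plan <- plan$repeats[[r]]
    y_true <- character(0)
    y_pred <- character(0)
    for (fi in seq_along(rep_plan$outer_folds)) {
      fold <- rep_plan$outer_folds[[fi]]
      inner_idx <- lapply(fold$inner_folds, function(f) {
        list(train = idx_of(f$train), test = idx_of(f$test))
      })
      hp <- grid_search(inner_idx, X, y, grid)
      tr <- idx_of(fold$train)
      te <- idx_of(fold$test)
      model <- train_svm(X[tr, , drop = FALSE], y[tr],
                         list(C = hp$C, gamma = hp$gamma))
      y_pred <- c(y_pred, predict(model, X[te, , drop = FALSE]))
      y_true <- c(y_true, y[te])
      hp_rows[[length(hp_rows) + 1L]] <- tibble::tibble(
        repeat_id = r, fold = fi, C = hp$C, gamma = hp$gamma,
        inner_f1 = hp$f1
      )
    }
    per_repeat[[r]] <- compute_metrics(confusion(y_true, y_pred))
  }

  metric_tbl <- dplyr::bind_rows(lapply(seq_along(per_repeat), function(r) {
    m <- per_repeat[[r]]
    tibble::tibble(
      repeat_id = r, precision = m$precision, recall = m$recall,
      f1 = m$f1, specificity = m$specificity
    )
  }))
  structure(
    list(
      protocol = plan$protocol,
      prevalence = plan$prevalence,
      seed = plan$seed,
      n_features = ncol(X),
      metrics = metric_tbl,
      selected_hyperparameters = dplyr::bind_rows(hp_rows)
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s%s, %d repeat(s), %d features\n",
              x$protocol,
              if (!is.na(x$prevalence)) sprintf(" @ %g%% prevalence", 100 * x$prevalence) else "",
              nrow(x$metrics), x$n_features))
  print(glance(x))
  invisible(x)
}

#' Per-repeat metrics of a CV report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return Tibble with one row per repeat: precision, recall, f1,
#'   specificity (fractions in `[0, 1]`).
#' @export
tidy.cv_report <- function(x, ...) {
  x$metrics
}

#' One-row summary (mean and sd over repeats) of a CV report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return One-row tibble with `<metric>_mean` / `<metric>_sd` columns (%).
#' @export
glance.cv_report <- function(x, ...) {
  m <- x$metrics[, c("precision", "recall", "f1", "specificity")]
  out <- c(
    as.list(100 * colMeans(m)),
    stats::setNames(as.list(100 * apply(m, 2, stats::sd)),
                    paste0(names(m), "_sd"))
  )
  names(out)[1:4] <- paste0(names(m), "_mean")
  tibble::as_tibble(out[order(names(out))])
}

#' Plot per-repeat CV metrics
#'
#' Dot plot of precision, recall, f1 and specificity per repeat with the
#' across-repeat mean marked.
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"repeat_id",
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = 100 * .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$repeat_id)),
                        position = ggplot2::position_jitter(width = 0.08, height = 0),
                        size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = "metric (%)", colour = "repeat",
      title = sprintf("Nested CV (%s)", object$protocol)
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Serialize a CV report
#'
#' Writes the report as JSON (machine-readable) and, optionally, a
#' plain-text summary table with metrics as rows.
#'
#' @param report A `cv_report`.
#' @param json_path Output JSON path.
#' @param table_path Optional path for the human-readable table.
#' @return `json_path`, invisibly.
#' @export
write_cv_report <- function(report, json_path, table_path = NULL) {
  payload <- list(
    protocol = report$protocol,
    prevalence = report$prevalence,
    seed = report$seed,
    n_features = report$n_features,
    per_repeat = report$metrics,
    summary = glance(report),
    selected_hyperparameters = report$selected_hyperparameters
  )
  jsonlite::write_json(payload, json_path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  if (!is.null(table_path)) {
    writeLines(format_cv_table(report), table_path)
  }
  invisible(json_path)
}

#' Format one or more CV reports as a text table
#'
#' Rows are f1, recall, precision and specificity (mean +/- sd, %);
#' columns are the supplied experiments.
#'
#' @param ... `cv_report` objects (named arguments become column headers).
#' @return Character vector of table lines.
#' @export
format_cv_table <- function(...) {
  reports <- list(...)
  labels <- names(reports)
  if (is.null(labels)) labels <- rep("", length(reports))
  labels <- ifelse(labels == "",
                   vapply(reports, function(r) {
                     if (!is.na(r$prevalence)) sprintf("%g%%", 100 * r$prevalence)
                     else r$protocol
                   }, character(1)),
                   labels)
  rows <- c("f1", "recall", "precision", "specificity")
  cells <- vapply(reports, function(r) {
    g <- glance(r)
    vapply(rows, function(m) {
      s <- g[[paste0(m, "_sd")]]
      if (is.na(s)) { # single repeat: no spread to report
        sprintf("%.1f", g[[paste0(m, "_mean")]])
      } else {
        sprintf("%.1f ± %.1f", g[[paste0(m, "_mean")]], s)
      }
    }, character(1))
  }, character(length(rows)))
  cells <- matrix(cells, nrow = length(rows))
  widths <- pmax(nchar(labels), apply(nchar(cells), 2, max))
  header <- paste0(
    formatC("Parameter", width = 12, flag = "-"),
    paste(mapply(formatC, labels, width = widths + 2), collapse = "")
  )
  body <- vapply(seq_along(rows), function(i) {
    paste0(
      formatC(rows[i], width = 12, flag = "-"),
      paste(mapply(formatC, cells[i, ], width = widths + 2), collapse = "")
    )
  }, character(1))
  c(header, body)
}
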