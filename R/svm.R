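#' Gaussian RBF kernel
#'
#' `K(x, xi) = exp(-gamma * ||x - xi||^2)`: symmetric, in (0, 1], equal to 1
#' exactly when the arguments coincide.
#'
#' @param x,xi Numeric vectors of equal length.
#' @param gamma Positive kernel width coefficient.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, xi, gamma) {
  if (length(x) != length(xi)) {
    stop("rbf_kernel: length mismatch", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0) {
    stop("rbf_kernel: gamma must be positive", call. = FALSE)
  }
  exp(-gamma * sum((x - xi)^2))
}

# pairwise kernel matrix between rows of A (n x p) and B (m x p)
rbf_kernel_matrix <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Per-feature standardization parameters
#'
#' Estimates column means and standard deviations on training data only
#' (the RBF kernel needs comparable feature scales). Zero-variance features
#' are flagged and their sd set to 1.
#'
#' @param X Numeric training matrix (rows = subjects).
#' @return List with `mean`, `sd`, `flagged` (class `standardization`).
#' @export
fit_standardization <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  flagged <- !is.finite(sdev) | sdev <= 0
  sdev[flagged] <- 1
  structure(list(mean = mu, sd = sdev, flagged = flagged),
            class = "standardization")
}

#' @rdname fit_standardization
#' @param params A `standardization` object.
#' @export
apply_standardization <- function(X, params) {
  stopifnot(inherits(params, "standardization"))
  sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Fit the soft-margin RBF SVM
#'
#' Solves the soft-margin dual with the Gaussian kernel through libsvm's
#' sequential minimal optimization (via e1071) and repackages the solution
#' as an explicit kernel expansion: support vectors, signed dual
#' coefficients `alpha_i y_i`, and bias `b`. RHD is the positive class;
#' the stored coefficients satisfy the box constraint `|alpha_i| <= C` and
#' the equality constraint `sum(alpha_i y_i) = 0` up to solver tolerance.
#'
#' @param X Standardized numeric feature matrix.
#' @param y Labels, `"RHD"`/`"HC"` (or a factor thereof).
#' @param hp List with positive elements `C` and `gamma`.
#' @param standardization Optional `standardization` object to carry along
#'   (so the model is self-contained for raw inputs).
#' @return An object of class `pcg_svm`.
#' @export
fit_svm <- function(X, y, hp, standardization = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) {
    stop("degenerate training set: only one class present", call. = FALSE)
  }
  if (!all(y %in% c("RHD", "HC"))) {
    stop("labels must be 'RHD' or 'HC'", call. = FALSE)
  }
  stopifnot(hp$C > 0, hp$gamma > 0)
  yf <- factor(y, levels = c("RHD", "HC"))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "radial",
                    gamma = hp$gamma, cost = hp$C, scale = FALSE,
                    tolerance = 1e-3)
  sv <- as.matrix(fit$SV)
  coefs <- as.numeric(fit$coefs)
  b <- -fit$rho
  # canonicalize sign so that positive margins mean RHD
  d_train <- as.numeric(rbf_kernel_matrix(X, sv, hp$gamma) %*% coefs + b)
  if (mean(d_train[y == "RHD"]) < mean(d_train[y == "HC"])) {
    coefs <- -coefs
    b <- -b
  }
  structure(
    list(
      support_vectors = sv,
      dual_coefficients = coefs,
      bias = b,
      gamma = hp$gamma,
      C = hp$C,
      standardization = standardization,
      feature_names = colnames(X),
      n_train = nrow(X)
    ),
    class = "pcg_svm"
  )
}

#' SVM decision function
#'
#' Evaluates the kernel expansion
#' `g(x) = sum_i alpha_i y_i K(x, x_i) + b` for rows of `X` (which must be
#' on the same standardized scale as the support vectors). Positive margins
#' indicate RHD.
#'
#' @param model A `pcg_svm`.
#' @param X Matrix (or single vector) of standardized feature rows.
#' @return Numeric vector of signed margins.
#' @export
decision_function <- function(model, X) {
  stopifnot(inherits(model, "pcg_svm"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$support_vectors)) {
    stop("decision_function: feature-length mismatch", call. = FALSE)
  }
  as.numeric(rbf_kernel_matrix(X, model$support_vectors, model$gamma) %*%
               model$dual_coefficients + model$bias)
}

#' @export
predict.pcg_svm <- function(object, newdata, standardize = !is.null(object$standardization), ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (standardize) {
    newdata <- apply_standardization(newdata, object$standardization)
  }
  g <- decision_function(object, newdata)
  # tie at exactly 0 goes to HC (conservative for precision)
  ifelse(g > 0, "RHD", "HC")
}

#' @export
print.pcg_svm <- function(x, ...) {
  cat(sprintf(
    "<pcg_svm> RBF SVM: C=%g gamma=%g, %d support vectors (of %d), bias %.4g\n",
    x$C, x$gamma, nrow(x$support_vectors), x$n_train, x$bias
  ))
  invisible(x)
}

#' Train on raw features with internal standardization
#'
#' Convenience wrapper used by the cross-validation engine: standardizes
#' with training statistics, fits, and returns a model that accepts raw
#' feature rows in `predict()`.
#'
#' @inheritParams fit_svm
#' @export
train_svm <- function(X, y, hp) {
  X <- as.matrix(X)
  std <- fit_standardization(X)
  fit_svm(apply_standardization(X, std), y, hp, standardization = std)
}

#' The hyperparameter grid
#'
#' The 5 x 5 search grid: `C` in (0.01, 0.1, 1, 10, 100) and `gamma` in
#' (0.0001, 0.001, 0.01, 0.1, 1).
#'
#' @return List with sorted numeric vectors `C` and `gamma`.
#' @export
default_grid <- function() {
  list(C = c(0.01, 0.1, 1, 10, 100),
       gamma = c(0.0001, 0.001, 0.01, 0.1, 1))
}

#' Inner-loop grid search maximizing pooled f1
#'
#' For every (C, gamma) pair, fits on each inner training set, predicts the
#' matching inner test set, pools all inner test predictions and scores the
#' pooled f1 (RHD positive). Returns the argmax; ties break to the smallest
#' C, then the smallest gamma (the smoother boundary).
#'
#' @param inner_folds List of `list(train = idx, test = idx)` index pairs.
#' @param X Raw feature matrix (standardization is re-fit per inner
#'   training set; no leakage into inner test rows).
#' @param y Labels.
#' @param grid List with vectors `C` and `gamma`.
#' @return List `C`, `gamma`, `f1`, and a tibble `scores` of all pairs.
#' @export
grid_search <- function(inner_folds, X, y, grid = default_grid()) {
  if (length(inner_folds) == 0L || length(grid$C) == 0L ||
      length(grid$gamma) == 0L) {
    stop("grid_search: empty grid or fold list", call. = FALSE)
  }
  X <- as.matrix(X)
  y <- as.character(y)
  cs <- sort(grid$C)
  gs <- sort(grid$gamma)
  best <- list(C = NA_real_, gamma = NA_real_, f1 = -Inf)
  rows <- list()
  for (C in cs) {
    for (gamma in gs) {
      yt <- character(0)
      yp <- character(0)
      for (fold in inner_folds) {
        m <- train_svm(X[fold$train, , drop = FALSE], y[fold$train],
                       list(C = C, gamma = gamma))
        yp <- c(yp, predict(m, X[fold$test, , drop = FALSE]))
        yt <- c(yt, y[fold$test])
      }
      f1 <- compute_metrics(confusion(yt, yp), warn = FALSE)$f1
      rows[[length(rows) + 1L]] <- tibble::tibble(C = C, gamma = gamma, f1 = f1)
      if (f1 > best$f1) best <- list(C = C, gamma = gamma, f1 = f1)
    }
  }
  c(best, list(scores = dplyr::bind_rows(rows)))
}

#' Serialize / restore a fitted SVM
#'
#' Self-contained JSON archive (support vectors, dual coefficients, bias,
#' hyperparameters, standardization, feature names, package version);
#' reloading reproduces decision values to 1e-12.
#'
#' @param model A `pcg_svm`.
#' @param path Output path.
#' @export
save_svm <- function(model, path) {
  stopifnot(inherits(model, "pcg_svm"))
  payload <- list(
    support_vectors = unclass(model$support_vectors),
    dual_coefficients = model$dual_coefficients,
    bias = model$bias,
    gamma = model$gamma,
    C = model$C,
    standardization = if (!is.null(model$standardization)) {
      list(mean = as.numeric(model$standardization$mean),
           sd = as.numeric(model$standardization$sd),
           flagged = model$standardization$flagged)
    },
    feature_names = model$feature_names,
    n_train = model$n_train,
    version = as.character(utils::packageVersion("pcgscreen"))
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_svm
#' @export
load_svm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- if (!is.null(p$standardization)) {
    structure(list(mean = p$standardization$mean,
                   sd = p$standardization$sd,
                   flagged = p$standardization$flagged),
              class = "standardization")
  }
  structure(
    list(
      support_vectors = as.matrix(p$support_vectors),
      dual_coefficients = p$dual_coefficients,
      bias = p$bias,
      gamma = p$gamma,
      C = p$C,
      standardization = std,
      feature_names = p$feature_names,
      n_train = p$n_train
    ),
    class = "pcg_svm"
  )
}
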