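two_clouds <- function(n = 20, sep = 6, p = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n, p) + sep,
             matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("f", 1:p)
  list(X = X, y = rep(c("RHD", "HC"), each = n))
}

test_that("the RBF kernel matches its closed forms and a brute-force sum", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), 0.5), 1)
  expect_equal(rbf_kernel(0, 1, 1), exp(-1))
  set.seed(2)
  x <- rnorm(31); z <- rnorm(31); g <- 0.037
  brute <- exp(-g * sum(vapply(seq_along(x), function(i) (x[i] - z[i])^2,
                               numeric(1))))
  expect_equal(rbf_kernel(x, z, g), brute, tolerance = 1e-12)
  expect_equal(rbf_kernel(x, z, g), rbf_kernel(z, x, g))
  expect_error(rbf_kernel(1:3, 1:4, 1), "length")
})

test_that("separable clouds train to 100% with all multipliers unbounded", {
  d <- two_clouds()
  m <- train_svm(d$X, d$y, list(C = 10, gamma = 0.5))
  expect_equal(unname(predict(m, d$X)), d$y)
  expect_true(all(abs(m$dual_coefficients) < 10 - 1e-6))
})

test_that("the RBF machine solves XOR", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c("HC", "RHD", "RHD", "HC")
  m <- train_svm(X, y, list(C = 100, gamma = 1))
  expect_equal(unname(predict(m, X)), y)
})

test_that("dual constraints hold on every fit", {
  for (seed in 1:5) {
    d <- two_clouds(n = 15, sep = 1.5, seed = seed) # overlapping classes
    m <- train_svm(d$X, d$y, list(C = 1, gamma = 0.2))
    expect_true(all(abs(m$dual_coefficients) <= 1 + 1e-6))
    expect_lt(abs(sum(m$dual_coefficients)), 1e-6)
  }
})

test_that("stored expansion reproduces decisions and margins", {
  d <- two_clouds(n = 25, sep = 4, seed = 3)
  std <- fit_standardization(d$X)
  Xs <- apply_standardization(d$X, std)
  m <- fit_svm(Xs, d$y, list(C = 100, gamma = 0.3))
  g <- decision_function(m, Xs)
  # hand-rolled evaluation of the kernel expansion, point by point
  g_brute <- vapply(seq_len(nrow(Xs)), function(i) {
    sum(vapply(seq_len(nrow(m$support_vectors)), function(j) {
      m$dual_coefficients[j] *
        rbf_kernel(Xs[i, ], m$support_vectors[j, ], m$gamma)
    }, numeric(1))) + m$bias
  }, numeric(1))
  expect_equal(g, g_brute, tolerance = 1e-6)
  # hard-margin support vectors sit on or outside the unit margin
  free_sv <- abs(m$dual_coefficients) < 100 - 1e-6
  sv_margins <- abs(decision_function(m, m$support_vectors))
  expect_true(all(sv_margins[free_sv] > 1 - 1e-3))
})

test_that("far from all support vectors the decision tends to the bias", {
  d <- two_clouds(n = 10, sep = 3, seed = 4)
  m <- train_svm(d$X, d$y, list(C = 1, gamma = 5))
  far <- matrix(c(100, -100), 1, 2)
  g <- decision_function(m, apply_standardization(far, m$standardization))
  expect_equal(g, m$bias, tolerance = 1e-6)
})

test_that("predictions agree with an independent SVM implementation", {
  d <- two_clouds(n = 40, sep = 2, p = 5, seed = 5)
  std <- fit_standardization(d$X)
  Xs <- apply_standardization(d$X, std)
  m <- fit_svm(Xs, d$y, list(C = 1, gamma = 0.1))
  set.seed(6)
  Xt <- matrix(rnorm(200 * 5, mean = 1), 200, 5)
  colnames(Xt) <- colnames(d$X)
  Xts <- apply_standardization(Xt, std)
  mine <- ifelse(decision_function(m, Xts) > 0, "RHD", "HC")
  ref <- kernlab::ksvm(Xs, factor(d$y), type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = 0.1), C = 1, scaled = FALSE)
  theirs <- as.character(kernlab::predict(ref, Xts))
  expect_gte(mean(mine == theirs), 0.99)
})

test_that("serialization round-trips decision values to 1e-12", {
  d <- two_clouds(n = 20, sep = 2, seed = 7)
  m <- train_svm(d$X, d$y, list(C = 10, gamma = 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  save_svm(m, path)
  m2 <- load_svm(path)
  set.seed(8)
  Xt <- matrix(rnorm(40), 20, 2)
  g1 <- decision_function(m, apply_standardization(Xt, m$standardization))
  g2 <- decision_function(m2, apply_standardization(Xt, m2$standardization))
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_svm(X, rep("HC", 10), list(C = 1, gamma = 1)),
               "one class")
  d <- two_clouds(n = 5)
  m <- train_svm(d$X, d$y, list(C = 1, gamma = 1))
  expect_error(decision_function(m, matrix(0, 1, 5)), "mismatch")
})

test_that("zero-variance features are flagged and neutralised", {
  X <- cbind(rnorm(10), rep(2, 10))
  std <- fit_standardization(X)
  expect_true(std$flagged[2])
  expect_equal(std$sd[2], 1)
  Xs <- apply_standardization(X, std)
  expect_true(all(is.finite(Xs)))
})

test_that("grid search scores all pairs and breaks ties toward smooth models", {
  d <- gaussian_features(12, 12, delta = 4, seed = 9)
  X <- as.matrix(d[, -(1:2)])
  folds <- lapply(1:3, function(i) {
    test <- seq(i, nrow(X), by = 3)
    list(train = setdiff(seq_len(nrow(X)), test), test = test)
  })
  gs <- grid_search(folds, X, d$label)
  expect_equal(nrow(gs$scores), 25)
  # fully separable: many pairs reach f1 = 1; the winner must be the
  # smallest C, then smallest gamma, among them
  top <- gs$scores[gs$scores$f1 == max(gs$scores$f1), ]
  expect_equal(gs$C, min(top$C))
  expect_equal(gs$gamma, min(top$gamma[top$C == gs$C]))
  expect_error(grid_search(list(), X, d$label), "empty")
})

test_that("grid search finds the wide kernel a tight-cluster task needs", {
  # pairs of tight clusters of opposite class sit 0.5 apart while clusters
  # of the same class are far apart: only a narrow kernel (gamma = 1, the
  # largest in the grid) separates them; exhaustive scoring confirms
  set.seed(10)
  centers <- expand.grid(x = c(0, 8, 16), y = c(0, 8, 16))
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(
      rbind(matrix(rnorm(8, sd = 0.05), 4, 2),
            matrix(rnorm(8, sd = 0.05), 4, 2) + 0.5),
      rep(c(1, 0), each = 4)
    )
  }))
  X <- pts[, 1:2] + as.matrix(centers)[rep(seq_len(9), each = 8), ]
  colnames(X) <- c("f1", "f2")
  y <- ifelse(pts[, 3] == 1, "RHD", "HC")
  folds <- lapply(1:4, function(i) {
    test <- seq(i, nrow(X), by = 4)
    list(train = setdiff(seq_len(nrow(X)), test), test = test)
  })
  gs <- grid_search(folds, X, y)
  expect_equal(gs$gamma, 1)
})
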