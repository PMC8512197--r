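subjects_tbl <- function(n_rhd, n_hc) {
  tibble::tibble(
    subject_id = c(sprintf("r%02d", seq_len(n_rhd)),
                   sprintf("h%02d", seq_len(n_hc))),
    label = c(rep("RHD", n_rhd), rep("HC", n_hc))
  )
}

test_that("HC count per fold follows round(1/p)", {
  expect_equal(hc_count_for_prevalence(0.05), 20L)
  expect_equal(hc_count_for_prevalence(0.025), 40L)
  expect_equal(hc_count_for_prevalence(0.10), 10L)
  expect_equal(hc_count_for_prevalence(0.20), 5L)
  expect_error(hc_count_for_prevalence(0), "prevalence")
  expect_error(hc_count_for_prevalence(0.6), "prevalence")
})

test_that("imbalanced plan has n outer folds with n-1 inner folds each", {
  subj <- subjects_tbl(6, 30)
  plan <- imbalanced_fold_plan(subj, p = 0.1, seed = 1, repeats = 2)
  expect_length(plan$repeats, 2)
  for (rep in plan$repeats) {
    expect_length(rep$outer_folds, 6)
    for (fold in rep$outer_folds) {
      expect_length(fold$inner_folds, 5)
      # 1 RHD + round(1/0.1) HC per evaluation fold
      expect_length(fold$test, 1 + 10)
      expect_equal(sum(startsWith(fold$test, "r")), 1)
      for (inner in fold$inner_folds) {
        expect_length(inner$test, 1 + 10)
      }
    }
  }
  # every RHD subject is evaluated exactly once per repeat
  outer_rhd <- vapply(plan$repeats[[1]]$outer_folds,
                      function(f) f$test[startsWith(f$test, "r")],
                      character(1))
  expect_setequal(outer_rhd, subj$subject_id[subj$label == "RHD"])
})

test_that("imbalanced plans are seed-deterministic and leakage-free", {
  subj <- subjects_tbl(5, 42)
  a <- imbalanced_fold_plan(subj, 0.05, seed = 9, repeats = 1)
  b <- imbalanced_fold_plan(subj, 0.05, seed = 9, repeats = 1)
  expect_identical(a, b)
  c2 <- imbalanced_fold_plan(subj, 0.05, seed = 10, repeats = 1)
  expect_false(identical(a$repeats[[1]]$outer_folds[[1]]$test,
                         c2$repeats[[1]]$outer_folds[[1]]$test))
  expect_true(audit_fold_plan(a))
})

test_that("insufficient HC pools raise a configuration error", {
  expect_error(imbalanced_fold_plan(subjects_tbl(4, 30), 0.025, seed = 1),
               "insufficient HC")
  expect_error(imbalanced_fold_plan(subjects_tbl(1, 50), 0.05, seed = 1),
               "RHD")
})

test_that("stratified folds preserve class proportions within one subject", {
  subj <- subjects_tbl(24, 27)
  plan <- stratified_fold_plan(subj, k = 10, seed = 2, repeats = 1)
  rep1 <- plan$repeats[[1]]
  expect_length(rep1$outer_folds, 10)
  test_rhd <- vapply(rep1$outer_folds, function(f) {
    sum(startsWith(f$test, "r"))
  }, numeric(1))
  test_hc <- vapply(rep1$outer_folds, function(f) {
    sum(startsWith(f$test, "h"))
  }, numeric(1))
  expect_true(all(test_rhd %in% c(2, 3))) # 24/10 rounded either way
  expect_true(all(test_hc %in% c(2, 3)))
  # partition property: every subject in exactly one outer test fold
  all_test <- unlist(lapply(rep1$outer_folds, `[[`, "test"))
  expect_setequal(all_test, subj$subject_id)
  expect_equal(anyDuplicated(all_test), 0)
  expect_true(audit_fold_plan(plan))
})

test_that("k equal to the smaller class size still partitions cleanly", {
  subj <- subjects_tbl(5, 12)
  plan <- stratified_fold_plan(subj, k = 5, seed = 3, repeats = 1)
  expect_length(plan$repeats[[1]]$outer_folds, 5)
  expect_true(audit_fold_plan(plan))
  expect_error(stratified_fold_plan(subjects_tbl(4, 12), k = 5, seed = 1),
               "at least k")
})

test_that("the audit catches a corrupted plan", {
  plan <- stratified_fold_plan(subjects_tbl(12, 12), k = 3, seed = 4,
                               repeats = 1)
  plan$repeats[[1]]$outer_folds[[1]]$train <-
    c(plan$repeats[[1]]$outer_folds[[1]]$train,
      plan$repeats[[1]]$outer_folds[[1]]$test[1])
  expect_error(audit_fold_plan(plan), "leakage")
})
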