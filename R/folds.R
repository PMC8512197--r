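# Subject-level nested cross-validation plans.
#
# A fold plan is fully materialized: every outer fold lists its training
# and test subject ids and carries its own inner folds, for each of the
# requested repeats, so a run is reproducible bit-for-bit from the plan.

#' HC subjects per evaluation fold for a target prevalence
#'
#' A single-RHD evaluation fold needs `round(1/p)` healthy controls so that
#' one case among them matches the target prevalence read as the RHD:HC
#' ratio: 20 HC at 5%, 40 HC at 2.5%.
#'
#' @param p Prevalence fraction, in (0, 0.5].
#' @return Integer count of HC subjects per fold.
#' @export
hc_count_for_prevalence <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 0.5) {
    stop("prevalence must be a single value in (0, 0.5]", call. = FALSE)
  }
  as.integer(round(1 / p))
}

new_fold_plan <- function(protocol, repeats, prevalence = NA_real_,
                          k = NA_integer_, seed) {
  structure(
    list(protocol = protocol, prevalence = prevalence, k = k,
         seed = seed, repeats = repeats),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  r1 <- x$repeats[[1]]
  cat(sprintf(
    "<fold_plan> %s%s: %d repeat(s), %d outer folds, %d inner folds each\n",
    x$protocol,
    if (!is.na(x$prevalence)) sprintf(" (prevalence %g%%)", 100 * x$prevalence) else "",
    length(x$repeats), length(r1$outer_folds),
    length(r1$outer_folds[[1]]$inner_folds)
  ))
  invisible(x)
}

split_subjects <- function(subjects) {
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: one record per subject is required",
         call. = FALSE)
  }
  list(
    rhd = subjects$subject_id[subjects$label == "RHD"],
    hc = subjects$subject_id[subjects$label == "HC"]
  )
}

#' Prevalence-controlled imbalanced nested CV plan
#'
#' Leave-one-RHD-subject-out in both loops: with n RHD subjects the plan
#' has n outer folds and, within each, n-1 inner folds. Per repeat the HC
#' subjects are first split once into an inner pool and an outer pool
#' (half each — both loops need the same number of HC slots per fold).
#' Each outer test set holds one RHD subject plus `round(1/p)` HCs drawn
#' uniformly (seeded) from the outer pool; HCs may recur across folds but
#' never within one. Each inner fold likewise holds one left-out RHD
#' subject plus `round(1/p)` inner-pool HCs. Outer-fold training sets are
#' the remaining RHD subjects plus the whole inner pool; inner-fold
#' training sets exclude that fold's test subjects.
#'
#' @param subjects Tibble with `subject_id` and `label` columns.
#' @param p Target prevalence in (0, 0.5].
#' @param seed Master seed; repeat r uses `seed + r - 1`.
#' @param repeats Number of repeats (default 5).
#' @return A `fold_plan`.
#' @export
imbalanced_fold_plan <- function(subjects, p, seed, repeats = 5) {
  m <- hc_count_for_prevalence(p)
  ids <- split_subjects(subjects)
  n_rhd <- length(ids$rhd)
  if (n_rhd < 2L) stop("need at least 2 RHD subjects", call. = FALSE)
  n_inner_pool <- ceiling(length(ids$hc) / 2)
  n_outer_pool <- length(ids$hc) - n_inner_pool
  if (min(n_inner_pool, n_outer_pool) < m) {
    stop(sprintf(
      "insufficient HC subjects: each pool needs >= %d, have %d/%d",
      m, n_inner_pool, n_outer_pool
    ), call. = FALSE)
  }
  reps <- lapply(seq_len(repeats), function(r) {
    rep_seed <- seed + r - 1L
    set.seed(rep_seed)
    inner_pool <- sample(ids$hc, n_inner_pool)
    outer_pool <- setdiff(ids$hc, inner_pool)
    outer_folds <- lapply(seq_len(n_rhd), function(i) {
      test_rhd <- ids$rhd[i]
      train_rhd <- ids$rhd[-i]
      test_hc <- sample(outer_pool, m)
      inner_folds <- lapply(seq_along(train_rhd), function(j) {
        inner_test_hc <- sample(inner_pool, m)
        list(
          train = c(train_rhd[-j], setdiff(inner_pool, inner_test_hc)),
          test = c(train_rhd[j], inner_test_hc)
        )
      })
      list(
        train = c(train_rhd, inner_pool),
        test = c(test_rhd, test_hc),
        inner_folds = inner_folds
      )
    })
    list(seed = rep_seed, outer_folds = outer_folds)
  })
  new_fold_plan("imbalanced", reps, prevalence = p, seed = seed)
}

# deal shuffled ids into k folds round-robin (sizes differ by at most 1;
# folds may be empty when a class has fewer members than k)
deal_folds <- function(ids, k) {
  shuffled <- sample(ids)
  split(shuffled, factor(rep(seq_len(k), length.out = length(shuffled)),
                         levels = seq_len(k)))
}

stratified_partition <- function(rhd, hc, k) {
  f_rhd <- deal_folds(rhd, k)
  f_hc <- deal_folds(hc, k)
  lapply(seq_len(k), function(i) c(f_rhd[[i]], f_hc[[i]]))
}

#' Stratified nested k-fold CV plan
#'
#' Outer stratified k-fold (class proportions preserved within one subject
#' per fold); each outer training set is again split into k stratified
#' inner folds for hyperparameter selection.
#'
#' @param subjects Tibble with `subject_id` and `label`.
#' @param k Folds in both loops (default 10).
#' @param seed Master seed; repeat r uses `seed + r - 1`.
#' @param repeats Number of repeats (default 5).
#' @return A `fold_plan`.
#' @export
stratified_fold_plan <- function(subjects, k = 10, seed, repeats = 5) {
  ids <- split_subjects(subjects)
  if (min(length(ids$rhd), length(ids$hc)) < k) {
    stop(sprintf("each class needs at least k = %d subjects", k),
         call. = FALSE)
  }
  reps <- lapply(seq_len(repeats), function(r) {
    rep_seed <- seed + r - 1L
    set.seed(rep_seed)
    outer_parts <- stratified_partition(ids$rhd, ids$hc, k)
    all_ids <- c(ids$rhd, ids$hc)
    outer_folds <- lapply(seq_len(k), function(i) {
      test <- outer_parts[[i]]
      train <- setdiff(all_ids, test)
      inner_parts <- stratified_partition(
        intersect(train, ids$rhd), intersect(train, ids$hc), k
      )
      inner_folds <- lapply(seq_len(k), function(j) {
        list(train = setdiff(train, inner_parts[[j]]),
             test = inner_parts[[j]])
      })
      list(train = train, test = test, inner_folds = inner_folds)
    })
    list(seed = rep_seed, outer_folds = outer_folds)
  })
  new_fold_plan("stratified_10fold", reps, k = as.integer(k), seed = seed)
}

#' Leakage audit of a fold plan
#'
#' Asserts subject-level separation on every fold of every repeat: no id in
#' both train and test of the same (outer or inner) fold, every inner fold
#' confined to its outer training partition, and every outer test subject
#' absent from all inner folds of that outer fold. Called automatically by
#' [run_nested_cv()].
#'
#' @param plan A `fold_plan`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
audit_fold_plan <- function(plan) {
  stopifnot(inherits(plan, "fold_plan"))
  for (rep in plan$repeats) {
    for (fold in rep$outer_folds) {
      if (length(intersect(fold$train, fold$test)) > 0) {
        stop("leakage: outer train/test overlap", call. = FALSE)
      }
      for (inner in fold$inner_folds) {
        if (length(intersect(inner$train, inner$test)) > 0) {
          stop("leakage: inner train/test overlap", call. = FALSE)
        }
        inner_all <- c(inner$train, inner$test)
        if (length(intersect(inner_all, fold$test)) > 0) {
          stop("leakage: outer test subject inside inner loop", call. = FALSE)
        }
        if (!all(inner_all %in% fold$train)) {
          stop("leakage: inner fold uses subjects outside outer training set",
               call. = FALSE)
        }
      }
    }
  }
  invisible(TRUE)
}
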