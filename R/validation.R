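# Fold assignment using the current RNG stream.  Per class: shuffle,
# allocate floor(n/k) rows to each of the k folds, drop the remainder
# (at most k-1 rows, i.e. at most one per fold).
fold_plan_rng <- function(labels, k) {
  labels <- as.integer(labels)
  folds <- rep(list(integer(0)), k)
  dropped <- list()
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    if (length(rows) < k)
      stop("class ", cl, " has ", length(rows),
           " members; cannot form ", k, " folds", call. = FALSE)
    rows <- sample(rows)
    m <- length(rows) %/% k
    keep <- rows[seq_len(m * k)]
    dropped[[as.character(cl)]] <- rows[-seq_len(m * k)]
    if (m * k == length(rows)) dropped[[as.character(cl)]] <- integer(0)
    idx <- matrix(keep, nrow = m, ncol = k)
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[, f])
  }
  structure(list(folds = folds, dropped = dropped, k = k,
                 labels = labels),
            class = "fold_plan")
}

#' Balanced stratified fold assignment
#'
#' Splits each outcome class independently into `k` folds of exactly equal
#' size, enforcing equality by dropping the remainder rows — at most one
#' per fold per class.  With 31 converters and 604 non-converters and
#' `k = 5` this yields folds of 6 converters (1 dropped) and 120
#' non-converters (4 dropped).
#'
#' @param labels binary outcome vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return an object of class `fold_plan`: `folds` (list of `k` row-index
#'   vectors), `dropped` (per-class dropped row indices), `k`, `labels`.
#' @export
balanced_stratified_folds <- function(labels, k = 5L, seed = 1L) {
  with_seed(seed, fold_plan_rng(labels, k))
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, length, 1L)
  cat("<fold_plan> k =", x$k, " fold sizes:", paste(sizes, collapse = ", "),
      " dropped:", sum(lengths(x$dropped)), "\n")
  invisible(x)
}

#' Export a fold plan as JSON
#'
#' @param plan a [balanced_stratified_folds()] plan.
#' @param path optional file path.
#' @return JSON string (invisibly when written to file).
#' @export
fold_plan_json <- function(plan, path = NULL) {
  js <- jsonlite::toJSON(list(k = plan$k, folds = plan$folds,
                              dropped = plan$dropped),
                         auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# Design matrix (with intercept) for a feature subset of a cohort.
subset_design <- function(cohort, features) {
  if (length(features) == 0L)
    return(matrix(1, nrow(cohort), 1L))
  cbind(1, as.matrix(cohort[paste0("v", features)]))
}

#' Repeated balanced stratified k-fold cross-validated AUC
#'
#' The model-scoring routine behind the genetic algorithm's fitness: for
#' each of `repeats` repetitions a fresh balanced stratified fold plan is
#' drawn, a logistic model on `features` is fitted on k−1 folds and scored
#' on the held-out fold, the k fold AUCs are averaged, and the per-repeat
#' means are averaged again.  The empty subset scores every case
#' identically (intercept-only model) and so returns AUC 0.5.
#'
#' @param cohort a cohort data.frame with `v1..v37` and `y`.
#' @param features integer battery indices (possibly empty).
#' @param k folds per repeat (default 5).
#' @param repeats number of repeats (default 5).
#' @param seed integer seed; the same seed reproduces the same value.
#' @return mean AUC across repeats.
#' @export
repeated_cv_auc <- function(cohort, features, k = 5L, repeats = 5L,
                            seed = 1L) {
  if (length(features) == 0L) return(0.5)
  Xd <- subset_design(cohort, features)
  y <- cohort$y
  with_seed(seed, {
    rep_means <- vapply(seq_len(repeats), function(r) {
      plan <- fold_plan_rng(y, k)
      aucs <- vapply(seq_len(k), function(f) {
        test <- plan$folds[[f]]
        train <- setdiff(unlist(plan$folds[-f]), test)
        sc <- fit_and_score(Xd[train, , drop = FALSE], y[train],
                            Xd[test, , drop = FALSE])
        auc_mw(sc, y[test])
      }, 0)
      mean(aucs)
    }, 0)
    mean(rep_means)
  })
}

#' Monte-Carlo cross-validated AUC
#'
#' Repeated stratified 80/20 holdout: in each run, 80% of each class trains
#' a logistic model on `features` and the held-out 20% is scored; the
#' `runs` holdout AUCs are averaged.  Used to report final models after the
#' search (default 1,000 runs).  Splits are stratified within class so that
#' heavily imbalanced cohorts always keep converters in the validation set.
#'
#' @inheritParams repeated_cv_auc
#' @param runs number of random splits (default 1000).
#' @param train_frac training fraction within each class (default 0.8).
#' @return mean held-out AUC.
#' @export
monte_carlo_cv <- function(cohort, features, runs = 1000L,
                           train_frac = 0.8, seed = 1L) {
  if (length(features) == 0L) return(0.5)
  Xd <- subset_design(cohort, features)
  y <- cohort$y
  pos <- which(y == 1L); neg <- which(y == 0L)
  n_tr_pos <- floor(length(pos) * train_frac)
  n_tr_neg <- floor(length(neg) * train_frac)
  if (n_tr_pos < 1L || length(pos) - n_tr_pos < 2L ||
      n_tr_neg < 1L || length(neg) - n_tr_neg < 2L)
    stop("classes too small for a ", train_frac, " split", call. = FALSE)
  with_seed(seed, {
    mean(vapply(seq_len(runs), function(i) {
      tr <- c(sample(pos, n_tr_pos), sample(neg, n_tr_neg))
      te <- setdiff(c(pos, neg), tr)
      sc <- fit_and_score(Xd[tr, , drop = FALSE], y[tr],
                          Xd[te, , drop = FALSE])
      auc_mw(sc, y[te])
    }, 0))
  })
}
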