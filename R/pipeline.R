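#' Batch of independent GA runs with a feature-frequency summary
#'
#' Runs the genetic algorithm `n_runs` times with distinct seeds derived
#' from `config$seed`, collects one row per run (Monte-Carlo AUC, subset
#' size, selected features) sorted by subset size then AUC, and tabulates
#' how often each battery feature appears among the best genomes.  The
#' study design uses 50 runs per task.
#'
#' @param cohort cohort data.frame.
#' @param config a [ga_config()]; `config$seed` is the master seed.
#' @param n_runs number of independent runs (default 50).
#' @param mc_runs Monte-Carlo splits per reported genome (default 1000).
#' @return a list of class `ga_batch`: `run_table` (data.frame `run`,
#'   `seed`, `mc_auc`, `n_vars`, `variables`), `frequency`
#'   (see [frequency_table()]) and `runs` (the individual [run_ga()]
#'   results, in run-table order).
#' @export
multi_run <- function(cohort, config, n_runs = 50L, mc_runs = 1000L) {
  seeds <- derive_seeds(config$seed, n_runs)
  runs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- s
    run_ga(cohort, cfg, mc_runs = mc_runs)
  })
  tab <- data.frame(
    seed = seeds,
    mc_auc = vapply(runs, `[[`, 0, "mc_auc"),
    n_vars = vapply(runs, function(r) length(r$selected), 0L),
    variables = vapply(runs, function(r)
      paste(r$selected, collapse = ";"), ""))
  o <- order(tab$n_vars, tab$mc_auc)
  tab <- tab[o, ]
  runs <- runs[o]
  tab <- cbind(run = seq_len(n_runs), tab)
  rownames(tab) <- NULL
  structure(list(run_table = tab,
                 frequency = frequency_table(runs),
                 runs = runs),
            class = "ga_batch")
}

#' Feature selection frequencies over a batch of GA runs
#'
#' @param runs list of [run_ga()] results, or a run table with a
#'   `variables` column of semicolon-separated indices.
#' @param n_bits battery size (default 37).
#' @return data.frame `feature`, `count`, `fraction`, with attribute
#'   `n_runs`.
#' @export
frequency_table <- function(runs, n_bits = 37L) {
  sel <- if (is.data.frame(runs)) {
    lapply(strsplit(runs$variables, ";"), as.integer)
  } else {
    lapply(runs, `[[`, "selected")
  }
  counts <- tabulate(unlist(sel), nbins = n_bits)
  structure(data.frame(feature = seq_len(n_bits), count = counts,
                       fraction = counts / length(sel)),
            n_runs = length(sel))
}

#' @export
print.ga_batch <- function(x, ...) {
  cat("<ga_batch>", nrow(x$run_table), "runs\n")
  print(utils::head(x$run_table, 10))
  top <- x$frequency[order(-x$frequency$fraction), ][1:5, ]
  cat("top features:",
      paste(sprintf("v%d (%.0f%%)", top$feature, 100 * top$fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Random-subset baseline
#'
#' For each requested subset size, scores `n_random` uniformly drawn
#' feature subsets by [repeated_cv_auc()] and compares the GA-selected
#' subsets of that size against them.  Significance is assessed two ways:
#' a paired t-test across size-matched (mean GA AUC, mean random AUC)
#' pairs, and a pooled two-sample t-test of all per-run GA AUCs against
#' all random-subset AUCs.
#'
#' @param cohort cohort data.frame.
#' @param ga_table a [multi_run()] run table (columns `mc_auc`, `n_vars`),
#'   or `NULL` to tabulate random subsets only.
#' @param sizes subset sizes to draw; defaults to the sizes present in
#'   `ga_table`.
#' @param n_random random subsets per size (default 100).
#' @param seed integer seed.
#' @param cv_seed seed for the scoring cross-validation.
#' @param ga_auc_col which GA AUC column to compare (default `"mc_auc"`).
#' @return list of class `baseline_comparison`: `by_size` (data.frame
#'   `size`, `ga_mean_auc`, `random_mean_auc`, `n_ga`, `n_random`),
#'   `paired` and `pooled` htest results (NULL when not computable), and
#'   `random_aucs` (per-size list).
#' @export
random_baseline <- function(cohort, ga_table = NULL, sizes = NULL,
                            n_random = 100L, seed = 1L, cv_seed = seed,
                            ga_auc_col = "mc_auc") {
  if (is.null(sizes)) {
    if (is.null(ga_table)) stop("need `sizes` or `ga_table`", call. = FALSE)
    sizes <- sort(unique(ga_table$n_vars))
  }
  if (any(sizes < 1L | sizes > 37L))
    stop("subset sizes must lie in 1..37", call. = FALSE)
  subset_seeds <- derive_seeds(seed, length(sizes))
  random_aucs <- lapply(seq_along(sizes), function(i) {
    subs <- with_seed(subset_seeds[i], {
      lapply(seq_len(n_random), function(j) sample.int(37L, sizes[i]))
    })
    vapply(subs, function(s)
      repeated_cv_auc(cohort, s, seed = cv_seed), 0)
  })
  names(random_aucs) <- as.character(sizes)
  ga_mean <- n_ga <- rep(NA_real_, length(sizes))
  if (!is.null(ga_table)) {
    for (i in seq_along(sizes)) {
      rows <- ga_table$n_vars == sizes[i]
      n_ga[i] <- sum(rows)
      if (any(rows)) ga_mean[i] <- mean(ga_table[[ga_auc_col]][rows])
    }
  }
  by_size <- data.frame(size = sizes, ga_mean_auc = ga_mean,
                        random_mean_auc = vapply(random_aucs, mean, 0),
                        n_ga = n_ga, n_random = n_random)
  paired <- pooled <- NULL
  if (!is.null(ga_table)) {
    ok <- !is.na(by_size$ga_mean_auc)
    if (sum(ok) >= 2L)
      paired <- stats::t.test(by_size$ga_mean_auc[ok],
                              by_size$random_mean_auc[ok], paired = TRUE)
    ga_all <- ga_table[[ga_auc_col]][ga_table$n_vars %in% sizes]
    rnd_all <- unlist(random_aucs[as.character(by_size$size[ok])])
    if (length(ga_all) >= 2L)
      pooled <- stats::t.test(ga_all, rnd_all)
  }
  structure(list(by_size = by_size, paired = paired, pooled = pooled,
                 random_aucs = random_aucs),
            class = "baseline_comparison")
}

#' @export
print.baseline_comparison <- function(x, ...) {
  cat("<baseline_comparison>\n")
  print(transform(x$by_size,
                  ga_mean_auc = round(ga_mean_auc, 3),
                  random_mean_auc = round(random_mean_auc, 3)))
  if (!is.null(x$paired))
    cat(sprintf("paired t over sizes: t = %.2f, p = %.3g\n",
                x$paired$statistic, x$paired$p.value))
  if (!is.null(x$pooled))
    cat(sprintf("pooled two-sample: t = %.2f, p = %.3g\n",
                x$pooled$statistic, x$pooled$p.value))
  invisible(x)
}

#' Backward stepwise elimination by AIC
#'
#' Starts from the logistic model on all candidate features and greedily
#' removes, at each step, the single feature whose removal lowers AIC the
#' most.  The natural stopping point — where no removal improves AIC — is
#' recorded, but elimination continues to a single feature so that a
#' snapshot subset of every visited size is available for size-matched
#' comparison with the GA.  Aliased (linearly dependent) columns are
#' dropped up front with a warning.
#'
#' @param cohort cohort data.frame.
#' @param features candidate battery indices (default all 37).
#' @return list of class `stepwise_path`: `steps` (data.frame `step`,
#'   `removed`, `aic_before`, `aic_after`), `snapshots` (named list,
#'   size -> feature indices), `stop_set` and `stop_size` (the AIC
#'   stopping point), `full_aic`.
#' @export
stepwise_backward_aic <- function(cohort, features = 1:37) {
  y <- cohort$y
  X <- as.matrix(cohort[paste0("v", features)])
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    drop_cols <- setdiff(seq_len(ncol(X) + 1L), keep_cols)
    drop_cols <- drop_cols[drop_cols > 1L]  # intercept always kept
    dropped <- features[drop_cols - 1L]
    warning("dropping aliased columns: ",
            paste0("v", dropped, collapse = ", "))
    features <- setdiff(features, dropped)
  }
  current <- sort(as.integer(features))
  aic_of <- function(feats) fit_logistic(
    cohort[paste0("v", feats)], y, feature_idx = feats)$aic
  aic_cur <- aic_of(current)
  full_aic <- aic_cur
  snapshots <- list()
  snapshots[[as.character(length(current))]] <- current
  steps <- data.frame(step = integer(), removed = integer(),
                      aic_before = numeric(), aic_after = numeric())
  stop_set <- NULL
  step <- 0L
  while (length(current) > 1L) {
    cand_aic <- vapply(seq_along(current), function(i)
      aic_of(current[-i]), 0)
    i_best <- which.min(cand_aic)
    if (is.null(stop_set) && cand_aic[i_best] >= aic_cur) {
      stop_set <- current  # AIC optimum: removing anything makes it worse
    }
    step <- step + 1L
    steps <- rbind(steps, data.frame(step = step,
                                     removed = current[i_best],
                                     aic_before = aic_cur,
                                     aic_after = cand_aic[i_best]))
    aic_cur <- cand_aic[i_best]
    current <- current[-i_best]
    snapshots[[as.character(length(current))]] <- current
  }
  if (is.null(stop_set)) stop_set <- current
  structure(list(steps = steps, snapshots = snapshots,
                 stop_set = stop_set, stop_size = length(stop_set),
                 full_aic = full_aic),
            class = "stepwise_path")
}

#' @export
print.stepwise_path <- function(x, ...) {
  cat("<stepwise_path>", nrow(x$steps), "eliminations; AIC stop at size",
      x$stop_size, ":", paste(x$stop_set, collapse = ";"), "\n")
  invisible(x)
}

#' Size-matched comparison of GA and stepwise feature sets
#'
#' For every subset size present in both the GA run table and the stepwise
#' elimination path, scores the best GA subset of that size and the
#' stepwise snapshot by [monte_carlo_cv()], and tests the per-size AUC
#' pairs with a paired t-test.
#'
#' @param ga_table a [multi_run()] run table.
#' @param stepwise a [stepwise_backward_aic()] path.
#' @param cohort cohort data.frame.
#' @param mc_runs Monte-Carlo splits per subset (default 1000).
#' @param seed scoring seed.
#' @return list of class `ga_stepwise_comparison`: `table` (data.frame
#'   `size`, `ga_variables`, `ga_auc`, `stepwise_variables`,
#'   `stepwise_auc`), `t_test` (paired htest, or NULL for a single size).
#' @export
compare_ga_stepwise <- function(ga_table, stepwise, cohort,
                                mc_runs = 1000L, seed = 1L) {
  sizes <- intersect(sort(unique(ga_table$n_vars)),
                     as.integer(names(stepwise$snapshots)))
  if (length(sizes) == 0L) stop("no common subset sizes", call. = FALSE)
  rows <- lapply(sizes, function(sz) {
    ga_rows <- ga_table[ga_table$n_vars == sz, ]
    ga_vars <- as.integer(strsplit(
      ga_rows$variables[which.max(ga_rows$mc_auc)], ";")[[1]])
    sw_vars <- stepwise$snapshots[[as.character(sz)]]
    data.frame(size = sz,
               ga_variables = paste(ga_vars, collapse = ";"),
               ga_auc = monte_carlo_cv(cohort, ga_vars, runs = mc_runs,
                                       seed = seed),
               stepwise_variables = paste(sw_vars, collapse = ";"),
               stepwise_auc = monte_carlo_cv(cohort, sw_vars,
                                             runs = mc_runs, seed = seed))
  })
  tab <- do.call(rbind, rows)
  tt <- NULL
  if (nrow(tab) >= 2L) {
    d <- tab$ga_auc - tab$stepwise_auc
    if (stats::sd(d) > 0) {
      tt <- stats::t.test(tab$ga_auc, tab$stepwise_auc, paired = TRUE)
    } else if (all(d == 0)) {
      # identical per-size scores: no evidence of a difference
      tt <- list(statistic = c(t = 0), p.value = 1,
                 method = "Paired t-test (degenerate: zero differences)")
    }
  }
  structure(list(table = tab, t_test = tt),
            class = "ga_stepwise_comparison")
}

#' @export
print.ga_stepwise_comparison <- function(x, ...) {
  cat("<ga_stepwise_comparison>\n")
  print(transform(x$table, ga_auc = round(ga_auc, 3),
                  stepwise_auc = round(stepwise_auc, 3)))
  if (!is.null(x$t_test))
    cat(sprintf("paired t: t = %.2f, p = %.3g\n",
                x$t_test$statistic, x$t_test$p.value))
  invisible(x)
}

#' Full-data model report for a selected feature subset
#'
#' Fits the logistic model on the complete cohort, reports coefficients,
#' Wald z-test p-values (with a Bonferroni-adjusted column for reference;
#' the primary p-values are unadjusted) and renders the model equation in
#' the `t = b0 + b1 v_i + ...` style.
#'
#' @param cohort cohort data.frame.
#' @param features non-empty battery indices.
#' @param label optional model name used in the equation string.
#' @return list of class `model_report`: `fit`, `coefficients` (data.frame
#'   `term`, `estimate`, `se`, `z`, `p`, `p_bonferroni`), `equation`.
#' @export
final_model_report <- function(cohort, features, label = "t") {
  if (length(features) == 0L) stop("empty feature subset", call. = FALSE)
  features <- sort(as.integer(features))
  fit <- fit_logistic(cohort[paste0("v", features)], cohort$y,
                      feature_idx = features)
  p <- wald_pvalues(fit)
  m <- length(p)
  tab <- data.frame(term = names(fit$coefficients),
                    estimate = unname(fit$coefficients),
                    se = unname(fit$se),
                    z = unname(fit$coefficients / fit$se),
                    p = unname(p),
                    p_bonferroni = pmin(unname(p) * m, 1))
  terms <- sprintf("%s%.2f%s",
                   ifelse(tab$estimate[-1] < 0, "-", "+"),
                   abs(tab$estimate[-1]), tab$term[-1])
  eq <- sprintf("%s=%.2f%s", label, tab$estimate[1],
                paste(terms, collapse = ""))
  structure(list(fit = fit, coefficients = tab, equation = eq),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report>", x$equation, "\n")
  print(transform(x$coefficients, estimate = signif(estimate, 3),
                  se = signif(se, 3), z = round(z, 2),
                  p = signif(p, 2), p_bonferroni = signif(p_bonferroni, 2)))
  invisible(x)
}

#' Per-feature group means with converter vs non-converter tests
#'
#' Tabulates the mean of every battery measure in each supplied group and,
#' for a designated pair of groups, tests each measure: Welch two-sample
#' t-test for continuous measures, chi-square for binary ones.  P-values
#' are unadjusted (a Bonferroni column is appended for reference).
#'
#' @param groups named list of cohort data.frames (columns `v1..v37`).
#' @param test_pair character vector of two group names to test against
#'   each other; defaults to the first two groups.
#' @param battery a [default_battery()] table.
#' @return data.frame with one row per measure: the per-group means, `test`
#'   (`"t"` or `"chisq"`), `p` and `p_bonferroni`.
#' @export
group_summary <- function(groups, test_pair = names(groups)[1:2],
                          battery = default_battery()) {
  if (length(groups) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(vapply(groups, nrow, 0L) == 0L))
    stop("empty group", call. = FALSE)
  stopifnot(all(test_pair %in% names(groups)))
  vcols <- feature_columns(battery)
  out <- data.frame(feature = battery$index, name = battery$name)
  for (g in names(groups))
    out[[g]] <- vapply(vcols, function(v) mean(groups[[g]][[v]]), 0)
  a <- groups[[test_pair[1]]]; b <- groups[[test_pair[2]]]
  res <- lapply(seq_len(nrow(battery)), function(i) {
    v <- vcols[i]
    if (battery$value_kind[i] == "binary") {
      tb <- rbind(table(factor(a[[v]], levels = 0:1)),
                  table(factor(b[[v]], levels = 0:1)))
      p <- tryCatch(
        suppressWarnings(stats::chisq.test(tb)$p.value),
        error = function(e) NA_real_)
      list(test = "chisq", p = p)
    } else {
      p <- tryCatch(stats::t.test(a[[v]], b[[v]])$p.value,
                    error = function(e) NA_real_)
      list(test = "t", p = p)
    }
  })
  out$test <- vapply(res, `[[`, "", "test")
  out$p <- vapply(res, `[[`, 0, "p")
  out$p_bonferroni <- pmin(out$p * nrow(battery), 1)
  out
}
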