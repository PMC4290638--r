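#' Configuration of a synthetic two-class cohort
#'
#' Describes a simulated cohort for one prediction task: class sizes,
#' per-class mean profiles, per-feature SDs, a correlation model for the
#' 36 continuous measures, and provenance bookkeeping for the participants
#' excluded before analysis (lost to follow-up, deceased, other dementias).
#' Defaults reproduce the study cohorts: 31 converters vs 604 non-converters
#' for the HC task (797 at baseline) and 47 vs 30 for the MCI task.
#'
#' @param task `"hc-conversion"` or `"mci-conversion"`.
#' @param n_positive,n_negative converter / non-converter counts; defaults
#'   are task-specific (31/604 and 47/30).
#' @param profiles list with `converter` and `nonconverter` mean vectors;
#'   defaults to [default_profiles()] for the task.
#' @param sd per-feature SDs (length 37); defaults to [default_sds()].
#' @param correlation correlation model, either
#'   `list(model = "block", r_in = 0.5, r_out = 0.2)` (features of the same
#'   source instrument correlate at `r_in`, others at `r_out`) or
#'   `list(model = "exchangeable", rho = r)`.
#' @param seed integer RNG seed for [generate_cohort()].
#' @param bookkeeping named counts of excluded baseline participants
#'   (`unavailable`, `deceased`, `other_dementia`); carried as provenance
#'   metadata only, never materialised as rows.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(task = c("hc-conversion", "mci-conversion"),
                          n_positive = NULL, n_negative = NULL,
                          profiles = NULL, sd = NULL,
                          correlation = list(model = "block",
                                             r_in = 0.5, r_out = 0.2),
                          seed = 1L,
                          bookkeeping = NULL) {
  task <- match.arg(task)
  defaults <- if (task == "hc-conversion") {
    list(np = 31L, nn = 604L,
         book = c(unavailable = 148L, deceased = 13L, other_dementia = 1L))
  } else {
    list(np = 47L, nn = 30L,
         book = c(unavailable = 49L, deceased = 13L, other_dementia = 3L))
  }
  n_positive <- as.integer(n_positive %||% defaults$np)
  n_negative <- as.integer(n_negative %||% defaults$nn)
  if (n_positive < 0L || n_negative < 0L)
    stop("class sizes must be non-negative", call. = FALSE)
  battery <- default_battery()
  profiles <- profiles %||% default_profiles(task)
  sd <- sd %||% default_sds(battery)
  if (any(sd <= 0)) stop("feature SDs must be positive", call. = FALSE)
  R <- correlation_matrix(battery, correlation)
  cont <- battery$value_kind == "continuous"
  # fail early on an invalid correlation model
  ch <- tryCatch(chol(R[cont, cont]), error = function(e) NULL)
  if (is.null(ch))
    stop("correlation model is not positive definite", call. = FALSE)
  structure(list(task = task,
                 n_positive = n_positive, n_negative = n_negative,
                 profiles = profiles, sd = sd,
                 correlation = correlation,
                 seed = as.integer(seed),
                 bookkeeping = bookkeeping %||% defaults$book,
                 battery = battery),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>", x$task, "\n",
      " converters:", x$n_positive,
      " non-converters:", x$n_negative, "\n",
      " correlation:", x$correlation$model, "\n")
  invisible(x)
}

#' Feature correlation matrix implied by a correlation model
#'
#' @param battery a [default_battery()] table.
#' @param correlation see [cohort_config()].
#' @return a 37 x 37 correlation matrix (binary features sit at identity).
#' @export
correlation_matrix <- function(battery, correlation) {
  p <- nrow(battery)
  R <- switch(correlation$model,
    block = {
      r_in <- correlation$r_in; r_out <- correlation$r_out
      same <- outer(battery$source, battery$source, "==")
      M <- matrix(r_out, p, p)
      M[same] <- r_in
      diag(M) <- 1
      M
    },
    exchangeable = {
      M <- matrix(correlation$rho, p, p)
      diag(M) <- 1
      M
    },
    stop("unknown correlation model: ", correlation$model, call. = FALSE))
  # binary measures are drawn independently of the Gaussian block
  bin <- battery$value_kind == "binary"
  R[bin, ] <- 0; R[, bin] <- 0; diag(R) <- 1
  R
}

#' Provenance of a configured cohort
#'
#' The analysis-set class sizes together with the excluded-participant
#' bookkeeping, and their sum: the size of the baseline cohort the analysis
#' set was drawn from (797 for the default HC task).
#'
#' @param config a [cohort_config()].
#' @return a list with `n_positive`, `n_negative`, the bookkeeping counts
#'   and `baseline_total`.
#' @export
cohort_provenance <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  b <- as.list(config$bookkeeping)
  c(list(n_positive = config$n_positive, n_negative = config$n_negative),
    b,
    list(baseline_total = config$n_positive + config$n_negative +
           sum(unlist(b))))
}

#' Restrict class separation to a planted feature subset
#'
#' Returns a copy of `config` whose two class profiles are identical except
#' on `subset`, where the converter mean is shifted by `delta` SD units
#' below the non-converter mean (cognitive scores fall with progression).
#' With `delta = 0` the two classes are exchangeable; the planted subset is
#' then the ground truth a feature-selection run should recover.
#'
#' @param config a [cohort_config()].
#' @param subset integer feature indices in 1..37.
#' @param delta non-negative effect size in per-feature SD units.
#' @return a modified `cohort_config`.
#' @export
plant_signal <- function(config, subset, delta) {
  stopifnot(inherits(config, "cohort_config"))
  subset <- as.integer(subset)
  if (length(subset) && (min(subset) < 1L || max(subset) > 37L))
    stop("planted subset indices must lie in 1..37", call. = FALSE)
  if (delta < 0) stop("`delta` must be non-negative", call. = FALSE)
  base <- as.numeric(config$profiles$nonconverter)
  names(base) <- paste0("v", 1:37)
  conv <- base
  conv[subset] <- conv[subset] - delta * config$sd[subset]
  config$profiles <- list(
    converter = structure(conv, group = "planted-converter",
                          class = c("group_profile", "numeric")),
    nonconverter = structure(base, group = "planted-nonconverter",
                             class = c("group_profile", "numeric")))
  config$planted <- list(subset = subset, delta = delta)
  config
}

# Draw one class: multivariate normal for continuous measures (single RNG
# stream, fixed column order), independent Bernoulli for binary ones.
draw_class <- function(n, mu, sds, chol_R, battery) {
  p <- nrow(battery)
  X <- matrix(NA_real_, n, p)
  cont <- which(battery$value_kind == "continuous")
  bin <- which(battery$value_kind == "binary")
  if (n > 0L) {
    Z <- matrix(stats::rnorm(n * length(cont)), n, length(cont))
    X[, cont] <- Z %*% chol_R
    X[, cont] <- sweep(X[, cont, drop = FALSE], 2, sds[cont], "*")
    X[, cont] <- sweep(X[, cont, drop = FALSE], 2, mu[cont], "+")
    for (j in bin) {
      pr <- min(max(mu[j], 0), 1)
      X[, j] <- stats::rbinom(n, 1L, pr)
    }
  }
  colnames(X) <- feature_columns(battery)
  X
}

#' Simulate a cohort table
#'
#' Generates `n_negative` non-converters followed by `n_positive`
#' converters.  Continuous measures are multivariate normal with the class
#' profile means, the configured SDs and the configured correlation model;
#' the binary Pass/Fail measure is Bernoulli with success probability equal
#' to the class mean clipped to \[0, 1\], drawn independently.  Fully
#' reproducible from `config$seed` (the caller's RNG state is untouched).
#'
#' @param config a [cohort_config()].
#' @return a data.frame with columns `id`, `v1`..`v37` and outcome `y`
#'   (1 = converted within 36 months), carrying the config as attribute
#'   `"config"`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  battery <- config$battery
  cont <- battery$value_kind == "continuous"
  R <- correlation_matrix(battery, config$correlation)
  chol_R <- chol(R[cont, cont])
  mu_n <- as.numeric(config$profiles$nonconverter)
  mu_p <- as.numeric(config$profiles$converter)
  X <- with_seed(config$seed, {
    Xn <- draw_class(config$n_negative, mu_n, config$sd, chol_R, battery)
    Xp <- draw_class(config$n_positive, mu_p, config$sd, chol_R, battery)
    rbind(Xn, Xp)
  })
  out <- data.frame(id = seq_len(nrow(X)), X,
                    y = rep(c(0L, 1L), c(config$n_negative, config$n_positive)))
  attr(out, "config") <- config
  out
}

#' Write / read a cohort as CSV
#'
#' Plain-text round trip: header `id,v1,...,v37,y`, feature values with six
#' significant digits, `y` in \{0, 1\}.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param path file path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns the cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort
  vcols <- grep("^v[0-9]+$", names(out))
  out[vcols] <- lapply(out[vcols], function(x) signif(x, 6))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path)
}

#' Load a cohort configuration from a YAML file
#'
#' Reads the scalar fields (task, class sizes, correlation model, seed,
#' bookkeeping); profiles and SDs are reconstructed from the packaged
#' defaults for the task.  The packaged defaults live in
#' `system.file("extdata", c("hc_conversion.yaml", "mci_conversion.yaml"),
#' package = "gacog")`.
#'
#' @param path YAML file path.
#' @return a [cohort_config()].
#' @export
cohort_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_config(task = y$task,
                n_positive = y$n_positive, n_negative = y$n_negative,
                correlation = y$correlation,
                seed = y$seed %||% 1L,
                bookkeeping = if (!is.null(y$bookkeeping))
                  unlist(y$bookkeeping) else NULL)
}
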