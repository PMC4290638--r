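#' Genetic-algorithm configuration
#'
#' Search parameters for the feature-subset genetic algorithm.  Defaults are
#' the study settings: population 50, mutation rate 10%, crossover rate 90%,
#' tournament size 2, 300 generations, compromise factor `rho = 0.085`, and
#' fitness scored by 5x5 repeated balanced stratified cross-validation.
#'
#' Under the default `"exclusive"` operator policy each selected parent pair
#' undergoes exactly one operator: two-point crossover (probability =
#' crossover rate), copy-plus-single-bit-mutation of each copy (probability
#' = mutation rate), or a plain copy with the remaining probability; the two
#' rates must sum to at most 1 (the default 0.90 + 0.10 leaves no plain
#' copies).  The `"independent"` policy applies
#' crossover with its rate and then mutates each child with the mutation
#' rate, for sensitivity checks.
#'
#' @param pop_size even population size >= 4 (default 50).
#' @param mutation_rate,crossover_rate operator probabilities (defaults
#'   0.10 / 0.90).
#' @param tournament_size parents per tournament (default 2).
#' @param generations number of generations (default 300).
#' @param rho compromise factor trading AUC against subset size
#'   (default 0.085).
#' @param cv_k,cv_repeats fitness cross-validation settings (defaults 5, 5).
#' @param n_bits genome length (default 37, the battery size).
#' @param seed integer seed for the run.
#' @param cache logical; memoise fitness per genome within a run.
#' @param operators `"exclusive"` (default) or `"independent"`.
#' @param target_fitness optional early-stop threshold; `NULL` (default)
#'   runs all generations.
#' @return an object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50L, mutation_rate = 0.10,
                      crossover_rate = 0.90, tournament_size = 2L,
                      generations = 300L, rho = 0.085,
                      cv_k = 5L, cv_repeats = 5L, n_bits = 37L,
                      seed = 1L, cache = TRUE,
                      operators = c("exclusive", "independent"),
                      target_fitness = NULL) {
  operators <- match.arg(operators)
  pop_size <- as.integer(pop_size)
  if (pop_size < 4L || pop_size %% 2L != 0L)
    stop("population size must be even and >= 4", call. = FALSE)
  if (operators == "exclusive" && crossover_rate + mutation_rate > 1 + 1e-12)
    stop("crossover + mutation rate must be <= 1 under the exclusive policy",
         call. = FALSE)
  structure(list(pop_size = pop_size, mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 tournament_size = as.integer(tournament_size),
                 generations = as.integer(generations), rho = rho,
                 cv_k = as.integer(cv_k), cv_repeats = as.integer(cv_repeats),
                 n_bits = as.integer(n_bits), seed = as.integer(seed),
                 cache = isTRUE(cache), operators = operators,
                 target_fitness = target_fitness),
            class = "ga_config")
}

#' Penalised-AUC fitness value
#'
#' The selection criterion `fitness = AUC + rho − rho * l / n`, where `l`
#' is the number of active features, `n` the genome length and `rho` the
#' compromise factor: at equal AUC a smaller subset always scores higher,
#' and the full subset (`l = n`) scores its AUC exactly.
#'
#' @param auc cross-validated AUC of the subset.
#' @param l number of selected features.
#' @param n genome length.
#' @param rho compromise factor.
#' @return the fitness value.
#' @examples
#' fitness_value(0.89, 3, 37, 0.085)  # 0.96811
#' @export
fitness_value <- function(auc, l, n, rho) auc + rho - rho * l / n

#' Random initial population
#'
#' `pop_size` genomes of `n_bits` i.i.d. Bernoulli(0.5) bits, drawn from
#' the current RNG stream (seed it, or use [run_ga()] which does).
#'
#' @param config a [ga_config()].
#' @return integer matrix, one genome per row.
#' @export
init_population <- function(config) {
  matrix(stats::rbinom(config$pop_size * config$n_bits, 1L, 0.5),
         nrow = config$pop_size, ncol = config$n_bits)
}

#' Fitness of one genome on a cohort
#'
#' Scores the genome's active features by [repeated_cv_auc()] and applies
#' the size penalty of [fitness_value()].  The all-zero genome is scored as
#' the intercept-only model (AUC 0.5), keeping the search space closed
#' under mutation.  `cv_seed` fixes the fold draws so a genome's fitness is
#' stable (and cacheable) within a run.
#'
#' @param genome 0/1 vector of length `config$n_bits`.
#' @param cohort cohort data.frame.
#' @param config a [ga_config()].
#' @param cv_seed integer seed for the fitness cross-validation.
#' @param cache_env optional environment memoising fitness by genome.
#' @return the fitness value.
#' @export
ga_fitness <- function(genome, cohort, config, cv_seed = config$seed,
                       cache_env = NULL) {
  key <- NULL
  if (!is.null(cache_env)) {
    key <- paste(genome, collapse = "")
    hit <- cache_env$values[[key]]
    if (!is.null(hit)) {
      cache_env$hits <- cache_env$hits + 1L
      return(hit)
    }
  }
  feats <- which(genome == 1L)
  auc <- repeated_cv_auc(cohort, feats, k = config$cv_k,
                         repeats = config$cv_repeats, seed = cv_seed)
  fit <- fitness_value(auc, length(feats), config$n_bits, config$rho)
  if (!is.null(cache_env)) {
    cache_env$values[[key]] <- fit
    cache_env$evals <- cache_env$evals + 1L
  }
  fit
}

#' Tournament selection of a parent pair
#'
#' Each parent is the fittest member of a random sample of
#' `tournament_size` individuals; the individual already chosen as the
#' first parent is excluded from the second tournament's pool (whose
#' tournament shrinks to the pool size if necessary).  Uses the current
#' RNG stream.
#'
#' @param population genome matrix (rows = individuals).
#' @param fitnesses fitness per row.
#' @param config a [ga_config()].
#' @return integer vector of two row indices (parent1, parent2).
#' @export
tournament_select <- function(population, fitnesses, config) {
  n <- nrow(population)
  ts <- config$tournament_size
  if (n < 2L || n < ts)
    stop("population too small for the tournament size", call. = FALSE)
  tour1 <- sample.int(n, ts)
  p1 <- tour1[which.max(fitnesses[tour1])]
  pool <- setdiff(seq_len(n), p1)
  tour2 <- pool[sample.int(length(pool), min(ts, length(pool)))]
  p2 <- tour2[which.max(fitnesses[tour2])]
  c(p1, p2)
}

#' Two-point crossover
#'
#' Two distinct cut points are drawn uniformly from the `n − 1` inter-bit
#' boundaries and the segment between them is exchanged between the
#' parents, producing two children.  (Exchanging the two outer segments
#' instead yields the same unordered pair of children.)
#'
#' @param parent1,parent2 equal-length 0/1 vectors.
#' @param cuts optional fixed pair of boundary positions (ascending, each
#'   in `1..n-1`); drawn randomly when `NULL`.
#' @return list of `child1`, `child2`.
#' @export
two_point_crossover <- function(parent1, parent2, cuts = NULL) {
  n <- length(parent1)
  if (length(parent2) != n) stop("parent length mismatch", call. = FALSE)
  if (is.null(cuts)) cuts <- sort(sample.int(n - 1L, 2L))
  seg <- (cuts[1L] + 1L):cuts[2L]
  child1 <- parent1; child2 <- parent2
  child1[seg] <- parent2[seg]
  child2[seg] <- parent1[seg]
  list(child1 = child1, child2 = child2)
}

#' Single-bit-flip mutation
#'
#' Flips one uniformly chosen bit, so the output is always at Hamming
#' distance exactly 1 from the input.
#'
#' @param genome 0/1 vector.
#' @param position optional fixed position; drawn uniformly when `NULL`.
#' @return mutated genome.
#' @export
bit_flip_mutation <- function(genome, position = NULL) {
  if (length(genome) == 0L) stop("empty genome", call. = FALSE)
  if (is.null(position)) position <- sample.int(length(genome), 1L)
  genome[position] <- 1L - genome[position]
  genome
}

#' Produce the next generation
#'
#' Repeats `pop_size / 2` times: draw a parent pair by tournament; apply
#' one operator per the configured policy (see [ga_config()]) and place the
#' two offspring in the new population.  Finally elitism: the previous
#' generation's best genome replaces the least-fit member of the new
#' population.  Uses the current RNG stream.
#'
#' @inheritParams tournament_select
#' @param cohort cohort data.frame.
#' @param cv_seed fitness CV seed (see [ga_fitness()]).
#' @param cache_env optional fitness cache environment.
#' @return list of `population` (matrix) and `fitnesses` for it.
#' @export
next_generation <- function(population, fitnesses, cohort, config,
                            cv_seed = config$seed, cache_env = NULL) {
  n <- nrow(population)
  newpop <- matrix(0L, n, config$n_bits)
  for (i in seq_len(n / 2L)) {
    pr <- tournament_select(population, fitnesses, config)
    p1 <- population[pr[1L], ]; p2 <- population[pr[2L], ]
    if (config$operators == "exclusive") {
      u <- stats::runif(1)
      if (u < config$crossover_rate) {
        ch <- two_point_crossover(p1, p2)
      } else if (u < config$crossover_rate + config$mutation_rate) {
        ch <- list(child1 = bit_flip_mutation(p1),
                   child2 = bit_flip_mutation(p2))
      } else {
        ch <- list(child1 = p1, child2 = p2)
      }
    } else {
      ch <- if (stats::runif(1) < config$crossover_rate)
        two_point_crossover(p1, p2) else list(child1 = p1, child2 = p2)
      if (stats::runif(1) < config$mutation_rate)
        ch$child1 <- bit_flip_mutation(ch$child1)
      if (stats::runif(1) < config$mutation_rate)
        ch$child2 <- bit_flip_mutation(ch$child2)
    }
    newpop[2L * i - 1L, ] <- ch$child1
    newpop[2L * i, ] <- ch$child2
  }
  newfit <- vapply(seq_len(n), function(i)
    ga_fitness(newpop[i, ], cohort, config, cv_seed, cache_env), 0)
  # elitism: previous best replaces the new population's least-fit member
  b <- which.max(fitnesses)
  w <- which.min(newfit)
  newpop[w, ] <- population[b, ]
  newfit[w] <- fitnesses[b]
  list(population = newpop, fitnesses = newfit)
}

#' Run the genetic algorithm once
#'
#' Evolves feature-subset genomes for `config$generations` generations and
#' returns the best genome ever seen, its penalised fitness, the
#' per-generation best/mean fitness trajectory (non-decreasing best, by
#' elitism), and the best subset's repeated-CV and Monte-Carlo AUCs.
#' Deterministic given `config$seed`.
#'
#' @param cohort cohort data.frame.
#' @param config a [ga_config()].
#' @param mc_runs Monte-Carlo splits used to report the best genome
#'   (default 1000).
#' @return an object of class `ga_run`: `best_genome`, `best_fitness`,
#'   `selected` (feature indices), `trajectory` (data.frame `generation`,
#'   `best`, `mean`), `cv_auc`, `mc_auc`, `seed`, `n_evaluations`,
#'   `cache_hits`.
#' @export
run_ga <- function(cohort, config, mc_runs = 1000L) {
  cache_env <- NULL
  if (config$cache) {
    cache_env <- new.env(parent = emptyenv())
    cache_env$values <- list()
    cache_env$hits <- 0L
    cache_env$evals <- 0L
  }
  res <- with_seed(config$seed, {
    cv_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    pop <- init_population(config)
    fits <- vapply(seq_len(config$pop_size), function(i)
      ga_fitness(pop[i, ], cohort, config, cv_seed, cache_env), 0)
    best_i <- which.max(fits)
    best_genome <- pop[best_i, ]
    best_fit <- fits[best_i]
    traj <- data.frame(generation = 0L, best = best_fit, mean = mean(fits))
    for (g in seq_len(config$generations)) {
      nx <- next_generation(pop, fits, cohort, config, cv_seed, cache_env)
      pop <- nx$population; fits <- nx$fitnesses
      gi <- which.max(fits)
      if (fits[gi] > best_fit) {
        best_fit <- fits[gi]
        best_genome <- pop[gi, ]
      }
      traj <- rbind(traj, data.frame(generation = g, best = best_fit,
                                     mean = mean(fits)))
      if (!is.null(config$target_fitness) &&
          best_fit >= config$target_fitness) break
    }
    list(best_genome = best_genome, best_fitness = best_fit,
         trajectory = traj, cv_seed = cv_seed)
  })
  selected <- which(res$best_genome == 1L)
  structure(list(
    best_genome = res$best_genome,
    best_fitness = res$best_fitness,
    selected = selected,
    trajectory = res$trajectory,
    cv_auc = repeated_cv_auc(cohort, selected, k = config$cv_k,
                             repeats = config$cv_repeats,
                             seed = res$cv_seed),
    mc_auc = monte_carlo_cv(cohort, selected, runs = mc_runs,
                            seed = res$cv_seed),
    seed = config$seed,
    n_evaluations = if (is.null(cache_env)) NA_integer_ else cache_env$evals,
    cache_hits = if (is.null(cache_env)) NA_integer_ else cache_env$hits),
    class = "ga_run")
}

#' @export
print.ga_run <- function(x, ...) {
  cat("<ga_run> seed", x$seed, "\n",
      " best subset:", paste(x$selected, collapse = ";"),
      sprintf("(l = %d)", length(x$selected)), "\n",
      sprintf("  fitness %.4f | CV AUC %.4f | MC AUC %.4f\n",
              x$best_fitness, x$cv_auc, x$mc_auc))
  invisible(x)
}

#' Serialize a GA run
#'
#' `ga_run_json()` writes the full result; `ga_run_tsv_row()` renders the
#' run-table row layout used by the study reports: run id, Monte-Carlo AUC,
#' subset size, semicolon-separated feature indices.
#'
#' @param run a [run_ga()] result.
#' @param id run number for the TSV row.
#' @param path optional file for the JSON form.
#' @return character (JSON or TSV line).
#' @export
ga_run_json <- function(run, path = NULL) {
  obj <- list(seed = run$seed, best_genome = run$best_genome,
              selected = run$selected, best_fitness = run$best_fitness,
              cv_auc = run$cv_auc, mc_auc = run$mc_auc,
              trajectory = run$trajectory,
              n_evaluations = run$n_evaluations)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname ga_run_json
#' @export
ga_run_tsv_row <- function(run, id = 1L) {
  paste(id, sprintf("%.2f", run$mc_auc), length(run$selected),
        paste(run$selected, collapse = ";"), sep = "\t")
}
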