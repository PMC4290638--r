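test_that("GA configuration is validated", {
  expect_error(ga_config(pop_size = 5), "even")
  expect_error(ga_config(pop_size = 2), "even")
  expect_error(ga_config(crossover_rate = 0.95, mutation_rate = 0.10),
               "<= 1")
  cfg <- ga_config()
  expect_equal(cfg$pop_size, 50L)
  expect_equal(cfg$mutation_rate, 0.10)
  expect_equal(cfg$crossover_rate, 0.90)
  expect_equal(cfg$tournament_size, 2L)
  expect_equal(cfg$generations, 300L)
  expect_equal(cfg$rho, 0.085)
})

test_that("initial population is Bernoulli(0.5) and seed-reproducible", {
  cfg <- ga_config(pop_size = 50, seed = 1)
  p1 <- withr::with_seed(1, init_population(cfg))
  p2 <- withr::with_seed(1, init_population(cfg))
  expect_identical(p1, p2)
  expect_equal(dim(p1), c(50L, 37L))
  expect_true(all(p1 %in% 0:1))
  big <- withr::with_seed(2, init_population(ga_config(pop_size = 1000)))
  expect_lt(abs(mean(rowSums(big)) - 18.5), 1)
})

test_that("fitness algebra: penalty vanishes at l = n and rho = 0", {
  expect_equal(fitness_value(0.77, 37, 37, 0.085), 0.77)
  expect_equal(fitness_value(0.77, 5, 37, 0), 0.77)
  # strict monotone decrease in subset size at fixed AUC
  f <- fitness_value(0.85, 1:37, 37, 0.085)
  expect_true(all(diff(f) < 0))
  # published-configuration value: AUC 0.89 with 3 of 37 features
  expect_equal(fitness_value(0.89, 3, 37, 0.085),
               0.89 + 0.085 * (1 - 3 / 37), tolerance = 1e-12)
  expect_equal(round(fitness_value(0.89, 3, 37, 0.085), 5), 0.96811)
})

test_that("genome fitness uses repeated-CV AUC and caches exactly", {
  co <- make_planted_cohort(delta = 1.5, n_pos = 40, n_neg = 40, seed = 5)
  cfg <- ga_config(seed = 3)
  g <- integer(37); g[c(3, 5, 18)] <- 1L
  direct <- fitness_value(repeated_cv_auc(co, c(3, 5, 18), seed = 123),
                          3, 37, cfg$rho)
  expect_equal(ga_fitness(g, co, cfg, cv_seed = 123), direct)
  cache <- new.env(); cache$values <- list(); cache$hits <- 0L
  cache$evals <- 0L
  f1 <- ga_fitness(g, co, cfg, cv_seed = 123, cache_env = cache)
  f2 <- ga_fitness(g, co, cfg, cv_seed = 123, cache_env = cache)
  expect_identical(f1, f2)
  expect_equal(cache$hits, 1L)
  expect_equal(cache$evals, 1L)
  # all-zero genome: intercept-only model, AUC pinned at 0.5
  expect_equal(ga_fitness(integer(37), co, cfg, cv_seed = 1),
               0.5 + cfg$rho)
})

test_that("tournament selection prefers fitter genomes and excludes parent1", {
  pop <- matrix(0L, 4, 37)
  fits <- c(1, 2, 3, 4)
  # exhaustive tournament: parent1 is the global best
  cfg_all <- ga_config(pop_size = 4, tournament_size = 4)
  sel <- withr::with_seed(1, tournament_select(pop, fits, cfg_all))
  expect_equal(sel[1], 4L)
  expect_error(tournament_select(pop, fits, ga_config(tournament_size = 5)),
               "tournament")
  # two-member population with singleton tours: parent2 is forced
  cfg1 <- ga_config(pop_size = 4, tournament_size = 1)
  withr::with_seed(2, {
    for (i in 1:20) {
      s <- tournament_select(matrix(0L, 2, 37), c(1, 2), cfg1)
      expect_equal(sort(s), c(1L, 2L))
    }
  })
  # empirical selection frequency increases with fitness rank;
  # closed form for parent1 with tour size 2 from 4: P(rank r) = (r-1)/6
  cfg2 <- ga_config(pop_size = 4, tournament_size = 2)
  picks <- withr::with_seed(3, vapply(seq_len(10000), function(i)
    tournament_select(pop, fits, cfg2)[1], 0L))
  freq <- tabulate(picks, 4) / 10000
  expect_true(all(diff(freq) > 0))
  expect_equal(freq, (0:3) / 6, tolerance = 0.03)
})

test_that("two-point crossover exchanges exactly the inner segment", {
  p1 <- rep(1L, 37); p2 <- rep(0L, 37)
  ch <- two_point_crossover(p1, p2, cuts = c(10, 20))
  expect_equal(sum(ch$child1), 27)  # lost bits 11..20
  expect_equal(sum(ch$child2), 10)  # gained bits 11..20
  # identical parents are a fixed point
  g <- withr::with_seed(5, rbinom(37, 1, 0.5))
  ch2 <- withr::with_seed(6, two_point_crossover(g, g))
  expect_equal(ch2$child1, g)
  expect_equal(ch2$child2, g)
  expect_error(two_point_crossover(p1, p2[-1]), "mismatch")
  # positionwise multiset invariant, and inner/outer swap equivalence
  withr::with_seed(7, {
    for (i in 1:50) {
      a <- rbinom(37, 1, 0.5); b <- rbinom(37, 1, 0.5)
      cuts <- sort(sample(36, 2))
      ch <- two_point_crossover(a, b, cuts = cuts)
      expect_equal(ch$child1 + ch$child2, a + b)
      # swapping the outer segments instead gives the same unordered pair
      seg <- (cuts[1] + 1):cuts[2]
      outer1 <- b; outer1[seg] <- a[seg]
      outer2 <- a; outer2[seg] <- b[seg]
      expect_setequal(
        c(paste(ch$child1, collapse = ""), paste(ch$child2, collapse = "")),
        c(paste(outer1, collapse = ""), paste(outer2, collapse = "")))
    }
  })
})

test_that("bit-flip mutation moves exactly one uniformly chosen bit", {
  g <- integer(37); g[35] <- 1L
  expect_equal(bit_flip_mutation(g, position = 35)[35], 0L)
  withr::with_seed(8, {
    for (i in 1:50) {
      g0 <- rbinom(37, 1, 0.5)
      g1 <- bit_flip_mutation(g0)
      expect_equal(sum(g0 != g1), 1)
      expect_equal(abs(sum(g1) - sum(g0)), 1)
    }
  })
  expect_error(bit_flip_mutation(integer(0)), "empty")
  # flip positions uniform over the genome: chi-square over 37,000 flips
  pos <- withr::with_seed(9, vapply(seq_len(37000), function(i) {
    which(bit_flip_mutation(integer(37)) == 1L)
  }, 0L))
  cs <- chisq.test(tabulate(pos, 37))
  expect_gt(cs$p.value, 0.001)
})

test_that("next generation conserves size, keeps the elite, and is closed under cloning", {
  co <- make_planted_cohort(delta = 2, n_pos = 30, n_neg = 30, seed = 6)
  cfg <- ga_config(pop_size = 8, seed = 2)
  withr::with_seed(2, {
    pop <- init_population(cfg)
    fits <- vapply(seq_len(8), function(i)
      ga_fitness(pop[i, ], co, cfg, cv_seed = 99), 0)
    nx <- next_generation(pop, fits, co, cfg, cv_seed = 99)
    expect_equal(dim(nx$population), dim(pop))
    best <- pop[which.max(fits), ]
    expect_true(any(apply(nx$population, 1, identical, as.integer(best))))
  })
  # crossover rate 1 on an identical-clone population: all clones persist
  clone <- integer(37); clone[c(1, 9, 20)] <- 1L
  pop_c <- matrix(rep(clone, 6), nrow = 6, byrow = TRUE)
  cfg_c <- ga_config(pop_size = 6, crossover_rate = 1, mutation_rate = 0,
                     seed = 3)
  nx_c <- withr::with_seed(3, next_generation(pop_c, rep(0.7, 6), co, cfg_c,
                                              cv_seed = 99))
  expect_true(all(apply(nx_c$population, 1, identical, clone)))
})

test_that("pure copying plus elitism keeps the best fitness constant", {
  co <- make_planted_cohort(delta = 1, n_pos = 30, n_neg = 30, seed = 7)
  cfg <- ga_config(pop_size = 6, crossover_rate = 0, mutation_rate = 0,
                   generations = 8, seed = 4)
  r <- run_ga(co, cfg, mc_runs = 20)
  expect_equal(length(unique(r$trajectory$best)), 1L)
})

test_that("GA runs are deterministic, monotone, and recover a dominant feature", {
  co <- make_planted_cohort(delta = 2.5, subset = 7, n_pos = 40, n_neg = 40,
                            seed = 8)
  cfg <- ga_config(pop_size = 16, generations = 12, seed = 5)
  r1 <- run_ga(co, cfg, mc_runs = 50)
  r2 <- run_ga(co, cfg, mc_runs = 50)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$mc_auc, r2$mc_auc)
  expect_true(all(diff(r1$trajectory$best) >= 0))
  expect_lte(r1$n_evaluations, cfg$pop_size * (cfg$generations + 1))
  # the planted feature dominates: selected in >= 9/10 short runs
  hits <- vapply(1:10, function(s) {
    cfg_s <- ga_config(pop_size = 16, generations = 12, seed = 100 + s)
    7 %in% run_ga(co, cfg_s, mc_runs = 10)$selected
  }, NA)
  expect_gte(sum(hits), 9)
  # smaller subset of equal AUC always has higher fitness at rho = 0.085
  expect_gt(fitness_value(0.9, 3, 37, 0.085), fitness_value(0.9, 5, 37, 0.085))
})

test_that("GA run serializes to JSON and the study TSV row shape", {
  co <- make_planted_cohort(delta = 2, subset = c(2, 4), n_pos = 30,
                            n_neg = 30, seed = 9)
  cfg <- ga_config(pop_size = 8, generations = 4, seed = 6)
  r <- run_ga(co, cfg, mc_runs = 20)
  js <- jsonlite::fromJSON(ga_run_json(r))
  expect_equal(js$selected, r$selected)
  expect_equal(js$mc_auc, r$mc_auc)
  row <- strsplit(ga_run_tsv_row(r, id = 3), "\t")[[1]]
  expect_equal(row[1], "3")
  expect_equal(row[3], as.character(length(r$selected)))
  expect_equal(row[4], paste(r$selected, collapse = ";"))
})
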