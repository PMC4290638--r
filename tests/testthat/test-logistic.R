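test_that("intercept-only fit recovers the logit of the positive rate", {
  y <- rep(c(0, 1), each = 25)
  f <- fit_logistic(matrix(numeric(0), 50, 0), y)
  expect_equal(unname(f$coefficients[1]), 0, tolerance = 1e-8)
  expect_true(f$converged)
  y2 <- rep(c(0, 1), c(30, 10))
  f2 <- fit_logistic(matrix(numeric(0), 40, 0), y2)
  expect_equal(unname(f2$coefficients[1]), qlogis(0.25), tolerance = 1e-6)
})

test_that("single binary predictor recovers the closed-form log odds ratio", {
  # 2x2 table a=30, b=10, c=10, d=30: beta1 = ln(ad/bc) = ln(9)
  x <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  y <- rep(c(1, 0, 1, 0), c(30, 10, 10, 30))
  f <- fit_logistic(matrix(x, ncol = 1), y)
  expect_equal(unname(f$coefficients[2]), log(9), tolerance = 1e-6)
})

test_that("coefficients, SEs and AIC agree with glm", {
  sim <- simulate_logistic(-1, c(0.8, -0.5, 0.3), 400, seed = 42)
  f <- fit_logistic(sim$X, sim$y)
  g <- glm(sim$y ~ sim$X, family = binomial())
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-6)
  expect_equal(unname(f$se), unname(sqrt(diag(vcov(g)))), tolerance = 1e-5)
  expect_equal(f$aic, AIC(g), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-6)
  # AIC identity
  expect_equal(f$aic, 2 * (length(f$coefficients)) - 2 * f$loglik)
})

test_that("parameter recovery from simulated data within 3 SE", {
  beta0 <- -2; beta <- c(1.2, -0.7, 0.4)
  sim <- simulate_logistic(beta0, beta, 5000, seed = 7)
  f <- fit_logistic(sim$X, sim$y)
  est <- f$coefficients; se <- f$se
  truth <- c(beta0, beta)
  expect_true(all(abs(est - truth) <= 3 * se))
})

test_that("degenerate designs are rejected or flagged", {
  expect_error(fit_logistic(matrix(rnorm(20), 10, 2), rep(1, 10)),
               "single class")
  X <- cbind(rnorm(40), 0)  # constant column aliased with the intercept
  y <- rep(0:1, 20)
  expect_error(fit_logistic(X, y), "rank-deficient")
  X2 <- matrix(rnorm(40), 40, 1)
  expect_error(fit_logistic(cbind(X2, 2 * X2), y), "aliased")
  expect_error(fit_logistic(matrix(c(NA, rnorm(39)), 40, 1), y), "missing")
  # complete separation: flagged, but scores still order the classes
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(0:1, each = 20)
  fs <- fit_logistic(matrix(xs, ncol = 1), ys)
  expect_true(fs$separation)
  expect_equal(auc_mw(linear_predictor(fs, matrix(xs, ncol = 1)), ys), 1)
})

test_that("linear predictor matches the published HC-conversion equation", {
  # model form t = 13.43 - 0.31 v1 - 0.27 v3 - 0.06 v5 - 0.18 v18
  fit <- structure(list(
    coefficients = c("(Intercept)" = 13.43, v1 = -0.31, v3 = -0.27,
                     v5 = -0.06, v18 = -0.18),
    se = rep(1, 5), feature_idx = c(1L, 3L, 5L, 18L)),
    class = "logistic_fit")
  expect_equal(linear_predictor(fit, c(0, 0, 0, 0)), 13.43)
  # at the HC-converter means, against an independent arithmetic check
  x <- c(28.23, 7.10, 51.23, 9.71)
  expected <- 13.43 + sum(c(-0.31, -0.27, -0.06, -0.18) * x)
  expect_equal(linear_predictor(fit, x), expected)
  df <- data.frame(v1 = 28.23, v3 = 7.10, v5 = 51.23, v18 = 9.71, v2 = 0)
  expect_equal(linear_predictor(fit, df), expected)
  expect_error(linear_predictor(fit, c(1, 2, 3)), "expected 4")
  expect_error(linear_predictor(fit, c(1, 2, 3, NA)), "missing")
})

test_that("predicted probabilities respect the logistic identities", {
  fit <- structure(list(
    coefficients = c("(Intercept)" = 0, v1 = 1), se = c(1, 1),
    feature_idx = 1L), class = "logistic_fit")
  expect_equal(predict_prob(fit, 0), 0.5)
  expect_equal(predict_prob(fit, log(3)), 0.75)
  expect_equal(predict_prob(fit, 800), 1)    # saturates, no overflow
  expect_equal(predict_prob(fit, -800), 0)
  # strictly increasing in t
  t <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(predict_prob(fit, matrix(t, ncol = 1))) > 0))
})

test_that("Wald p-values follow the normal-quantile identities", {
  fit <- structure(list(
    coefficients = c("(Intercept)" = 0, v1 = 1.96, v2 = 0),
    se = c(1, 1, 2), feature_idx = 1:2), class = "logistic_fit")
  p <- wald_pvalues(fit)
  expect_equal(unname(p[1]), 1)
  expect_equal(unname(p[3]), 1)
  expect_equal(unname(p[2]), 0.05, tolerance = 1e-3)
  fit$se[2] <- 0
  expect_error(wald_pvalues(fit), "zero standard error")
})

test_that("null effects give approximately uniform Wald p-values", {
  # 1,000 replicates of n = 2,000 with one pure-noise predictor
  pvals <- withr::with_seed(11, {
    vapply(seq_len(1000), function(i) {
      x <- rnorm(2000)
      y <- rbinom(2000, 1, 0.3)
      f <- fit_logistic(matrix(x, ncol = 1), y)
      wald_pvalues(f)[[2]]
    }, 0)
  })
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.001)
})

test_that("logistic fits serialize to JSON and back", {
  sim <- simulate_logistic(0, c(1), 100, seed = 3)
  f <- fit_logistic(sim$X, sim$y, feature_idx = 5L)
  js <- jsonlite::fromJSON(logistic_fit_json(f))
  expect_equal(js$aic, f$aic)
  expect_equal(js$feature_idx, 5L)
  expect_equal(js$coefficients$v5, unname(f$coefficients[2]))
})
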