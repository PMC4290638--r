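# Internal IRLS engine.  X must already contain the intercept column.
# Returns coefficients (rank-deficient columns pinned at 0 so the fit can
# still score), deviance, iteration count, convergence and separation flags.
# Tolerance: relative deviance change < 1e-8; cap 50 iterations; separation
# flagged when any |beta| crosses the divergence bound before convergence.
irls_logit <- function(X, y, maxit = 50L, tol = 1e-8, beta_bound = 15,
                       ridge = 0) {
  p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    if (ridge > 0) {
      Xa <- rbind(X * sw, diag(sqrt(ridge), p))
      za <- c(z * sw, numeric(p))
    } else {
      Xa <- X * sw
      za <- z * sw
    }
    f <- .lm.fit(Xa, za)
    co <- f$coefficients
    co[is.na(co)] <- 0
    beta[f$pivot] <- co
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(beta = beta, deviance = dev, iter = it, converged = converged,
       separation = max(abs(beta)) > beta_bound,
       rank = f$rank)
}

#' Fit a binomial logistic regression to a feature subset
#'
#' Maximum-likelihood logistic regression of a binary conversion outcome on
#' the selected feature columns, fitted by iteratively reweighted least
#' squares (cap 50 iterations, relative log-likelihood tolerance 1e-8).
#' Quasi-complete separation — likely with 31 converters against 604
#' non-converters — is flagged rather than treated as an error: the diverged
#' coefficients still order the cases, which is all AUC-based scoring needs.
#' When the weighted Hessian is numerically singular a tiny ridge
#' (lambda = 1e-6) is retried so standard errors remain defined.
#'
#' @param X numeric matrix or data.frame of predictor columns (no intercept
#'   column; zero columns gives an intercept-only model).
#' @param y binary outcome vector (0/1), at least one of each class.
#' @param feature_idx optional integer battery indices the columns of `X`
#'   correspond to; defaults to parsing `v<k>` column names, else `1:k`.
#' @return an object of class `logistic_fit`: `coefficients` (intercept
#'   first), `se`, `loglik`, `aic` (= 2(k+1) − 2 loglik), `converged`,
#'   `separation`, `feature_idx`, `n`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' y <- rbinom(100, 1, plogis(x[, 1]))
#' fit <- fit_logistic(x, y)
#' wald_pvalues(fit)
#' @export
fit_logistic <- function(X, y, feature_idx = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L && length(y) > 0L) X <- matrix(0, length(y), 0L)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (is.null(feature_idx)) {
    cn <- colnames(X)
    feature_idx <- if (!is.null(cn) && all(grepl("^v[0-9]+$", cn)))
      as.integer(sub("^v", "", cn)) else seq_len(ncol(X))
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; aliased columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  f <- irls_logit(Xd, y)
  # covariance from the final weighted cross-product; ridge retry if singular
  eta <- drop(Xd %*% f$beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(Xd * sqrt(w))
  V <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(V)) {
    f <- irls_logit(Xd, y, ridge = 1e-6)
    eta <- drop(Xd %*% f$beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    V <- chol2inv(chol(crossprod(Xd * sqrt(w)) + diag(1e-6, ncol(Xd))))
  }
  se <- sqrt(diag(V))
  ll <- -f$deviance / 2
  k <- ncol(Xd)
  beta <- f$beta
  names(beta) <- c("(Intercept)",
                   if (ncol(X)) paste0("v", feature_idx) else NULL)
  names(se) <- names(beta)
  structure(list(coefficients = beta, se = se,
                 loglik = ll, aic = 2 * k - 2 * ll,
                 converged = f$converged, separation = f$separation,
                 feature_idx = as.integer(feature_idx), n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> n =", x$n, " AIC =", round(x$aic, 2),
      if (x$separation) " [separation]" else "", "\n")
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Linear predictor of a fitted logistic model
#'
#' `t = beta0 + beta1 x1 + ... + betak xk` for one row or many.
#'
#' @param fit a [fit_logistic()] object (or a coefficient vector, intercept
#'   first).
#' @param newdata numeric vector of the fit's features (in `feature_idx`
#'   order), or a matrix/data.frame; data.frames may carry `v<k>` columns
#'   from which the fit's features are picked.
#' @return numeric vector of linear-predictor values.
#' @export
linear_predictor <- function(fit, newdata) {
  beta <- if (inherits(fit, "logistic_fit")) fit$coefficients else fit
  k <- length(beta) - 1L
  if (is.data.frame(newdata)) {
    want <- names(beta)[-1L]
    if (!all(want %in% names(newdata)))
      stop("newdata lacks features: ",
           paste(setdiff(want, names(newdata)), collapse = ", "),
           call. = FALSE)
    newdata <- as.matrix(newdata[want])
  } else if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != k)
    stop("expected ", k, " feature values, got ", ncol(newdata),
         call. = FALSE)
  if (anyNA(newdata)) stop("missing feature value", call. = FALSE)
  drop(beta[1L] + if (k) newdata %*% beta[-1L] else 0)
}

#' Conversion probability of a fitted logistic model
#'
#' `E(y) = exp(t) / (1 + exp(t))`, evaluated without overflow for extreme
#' linear predictors.
#'
#' @inheritParams linear_predictor
#' @return probabilities in (0, 1) (0/1 only in the limit).
#' @export
predict_prob <- function(fit, newdata) {
  stats::plogis(linear_predictor(fit, newdata))
}

#' Wald z-test p-values for each coefficient
#'
#' Two-sided normal test of each coefficient against 0:
#' `p = 2 (1 - Phi(|beta / se|))`.
#'
#' @param fit a converged [fit_logistic()].
#' @return named numeric vector of p-values (intercept included).
#' @export
wald_pvalues <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (any(fit$se == 0)) stop("zero standard error", call. = FALSE)
  2 * stats::pnorm(-abs(fit$coefficients / fit$se))
}

#' Serialize a logistic fit to JSON
#'
#' @param fit a [fit_logistic()] object.
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
logistic_fit_json <- function(fit, path = NULL) {
  obj <- list(coefficients = as.list(fit$coefficients),
              se = as.list(fit$se),
              loglik = fit$loglik, aic = fit$aic,
              converged = fit$converged, separation = fit$separation,
              feature_idx = fit$feature_idx, n = fit$n)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# Fast path used inside cross-validation loops: coefficients only.
# Xtr/Xte carry the intercept column already.
fit_and_score <- function(Xtr, ytr, Xte) {
  f <- irls_logit(Xtr, ytr)
  drop(Xte %*% f$beta)
}
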