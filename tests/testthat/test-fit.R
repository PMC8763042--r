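test_that("intercept-only fits recover the mean and the prior", {
  set.seed(21)
  y <- rpois(12, 5)
  f0 <- fit_cats(y, NULL, NULL, "poisson")
  expect_equal(f0$mu, rep(mean(y), 12), tolerance = 1e-8)
  pr <- toy_prior()
  y2 <- rpois(10, 60 * pr$pi)
  fo <- fit_cats(y2, NULL, offsets_log(pr), "poisson")
  expect_equal(predict_relative_abundance(fo), pr$pi, tolerance = 1e-6)
  expect_equal(sum(predict_relative_abundance(fo)), 1, tolerance = 1e-12)
})

test_that("coefficients agree with a generic ML optimizer started from zero", {
  set.seed(22)
  x <- cbind(rnorm(30), rnorm(30))
  off <- rnorm(30, 0, 0.3)
  y <- rpois(30, exp(0.8 + 0.4 * x[, 1] - 0.3 * x[, 2] + off))
  f <- fit_cats(y, x, off, "poisson", standardize = FALSE)
  nll <- function(b) -sum(dpois(y, exp(b[1] + x %*% b[2:3] + off), log = TRUE))
  ora <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(f)), ora$par, tolerance = 1e-5)

  yb <- rbinom(30, 1, plogis(-0.3 + 0.8 * x[, 1]))
  fb <- fit_cats(yb, x[, 1], NULL, cats_family("binomial"), "logit",
                 standardize = FALSE)
  nllb <- function(b) -sum(dbinom(yb, 1, plogis(b[1] + b[2] * x[, 1]),
                                  log = TRUE))
  orab <- optim(c(0, 0), nllb, method = "BFGS",
                control = list(maxit = 500, reltol = 1e-14))
  expect_equal(unname(coef(fb)), orab$par, tolerance = 1e-5)
})

test_that("canonical links with an intercept match totals, and likelihood is monotone in nesting", {
  set.seed(23)
  x <- cbind(a = rnorm(25), b = rnorm(25))
  y <- rpois(25, exp(1 + 0.5 * x[, 1]))
  f_p <- fit_cats(y, x, NULL, "poisson")
  expect_equal(sum(f_p$mu), sum(y), tolerance = 1e-6 * sum(y))
  yb <- rbinom(25, 1, plogis(0.5 * x[, 1]))
  f_b <- fit_cats(yb, x, NULL, cats_family("binomial"), "logit")
  expect_equal(sum(f_b$mu), sum(yb), tolerance = 1e-6 * max(1, sum(yb)))
  yg <- rnorm(25, 1 + x[, 1])
  f_g <- fit_cats(yg, x, NULL, "gaussian", "identity")
  expect_equal(sum(f_g$mu), sum(yg), tolerance = 1e-8 * abs(sum(yg)))

  # nested models: adding a trait never decreases the log-likelihood
  f1 <- fit_cats(y, x[, 1], NULL, "poisson")
  expect_gte(f_p$loglik + 1e-10, f1$loglik)
  f0 <- fit_cats(y, NULL, NULL, "poisson")
  expect_gte(f1$loglik + 1e-10, f0$loglik)
})

test_that("log-binomial fitting respects the mean constraint", {
  set.seed(24)
  S <- 200
  x <- rnorm(S)
  eta <- -1.8 + 0.0 * x
  y <- rbinom(S, 1, exp(eta))
  f <- fit_log_binomial(y, x, standardize = FALSE)
  expect_true(f$converged)
  # no true effect: slope within 2 Monte-Carlo SEs of zero
  expect_lt(abs(coef(f)[2]) / f$se[2], 2.5)
  expect_true(all(f$mu < 1))

  # multi-start oracle: no random start beats the returned likelihood
  nll <- function(b) {
    e <- b[1] + b[2] * x
    if (any(e >= 0)) return(Inf)
    -sum(y * e + (1 - y) * log1p(-exp(e)))
  }
  set.seed(25)
  best <- -Inf
  for (i in 1:20) {
    st <- c(runif(1, -4, -1), runif(1, -0.5, 0.5))
    if (nll(st) < Inf) {
      o <- tryCatch(
        constrOptim(st, nll, grad = NULL, ui = -cbind(1, x), ci = 1e-9),
        error = function(e) NULL)
      if (!is.null(o)) best <- max(best, -o$value)
    }
  }
  expect_gte(f$loglik - sum(lchoose(1, y)), best - 1e-4)

  expect_warning(fz <- fit_log_binomial(rep(0L, 20), rnorm(20)),
                 "degenerate|boundary")
  expect_true(fz$boundary)
})

test_that("negative binomial dispersion estimation recovers theta and caps cleanly", {
  set.seed(26)
  x <- rnorm(1000, 10, 3)
  y <- rnbinom(1000, size = 1, mu = exp(0.5 * x))
  f <- estimate_theta(y, x, standardize = FALSE)
  expect_gt(f$family$theta, 0.8)
  expect_lt(f$family$theta, 1.25)
  expect_equal(unname(coef(f)[2]), 0.5, tolerance = 0.1)
  expect_true(f$theta_estimated)

  # ML property: no theta on a grid around the estimate does better
  ll_at <- function(th)
    log_likelihood(y, f$mu, cats_family("negbin", theta = th))
  for (th in f$family$theta * c(0.85, 0.95, 1.05, 1.15))
    expect_gte(f$loglik + 1e-8, ll_at(th))

  # equi/under-dispersed counts: no overdispersion to estimate
  yp <- rep(c(4L, 5L, 6L), 100)
  expect_warning(fp <- estimate_theta(yp, NULL), "Poisson-like")
  expect_equal(fp$family$theta, 1e6)
})

test_that("hurdle fits decompose into presence and truncated parts", {
  y <- c(0, 0, 3, 1, 2)
  fh <- fit_hurdle(y, family = cats_family("trunc_poisson"))
  expect_equal(fh$binomial$mu, rep(3 / 5, 5), tolerance = 1e-6)
  # truncated intercept-only: truncated mean equals the positive-part mean
  expect_equal(truncation_adjust(fh$truncated$mu[1],
                                 cats_family("trunc_poisson")),
               2, tolerance = 1e-6)
  # grid-search oracle for the truncated intercept
  mu_grid <- seq(0.05, 5, by = 1e-4)
  ll_grid <- vapply(mu_grid, function(m)
    log_likelihood(c(3, 1, 2), rep(m, 3), "trunc_poisson"), numeric(1))
  expect_equal(fh$truncated$mu[1], mu_grid[which.max(ll_grid)],
               tolerance = 1e-3)
  expect_equal(fh$expected_abundance,
               fh$binomial$mu * truncation_adjust(
                 rep(fh$truncated$mu[1], 5), cats_family("trunc_poisson")),
               tolerance = 1e-10)
  expect_error(fit_hurdle(c(1, 2, 3), family = cats_family("trunc_poisson")),
               "no zeros")
  expect_error(fit_hurdle(c(0, 0, 0), family = cats_family("trunc_poisson")),
               "no positive")
})

test_that("hurdle slope recovery from simulated two-part data", {
  set.seed(28)
  S <- 500
  x <- rnorm(S)
  p <- plogis(0.3 + 1.0 * x)
  mu <- exp(0.4 + 0.5 * x)
  pres <- rbinom(S, 1, p)
  y <- integer(S)
  pos <- pres == 1
  y[pos] <- qpois(runif(sum(pos), dpois(0, mu[pos]), 1), mu[pos])  # truncated draws
  fh <- fit_hurdle(y, x, family = cats_family("trunc_poisson"),
                   standardize = FALSE, link_binomial = "logit")
  expect_lt(abs(coef(fh$binomial)[2] - 1.0) / fh$binomial$se[2], 2.5)
  expect_lt(abs(coef(fh$truncated)[2] - 0.5) / fh$truncated$se[2], 2.5)
})

test_that("relative-abundance predictions reproduce the prior only when link and offset agree", {
  pr <- toy_prior()
  set.seed(29)
  y <- rbinom(10, 1, 0.5)
  y[1:2] <- c(0, 1)
  # logit link fed log-prior offsets: systematic nonlinear departure
  f_bad <- suppressWarnings(
    fit_cats(y, NULL, offsets_log(pr), cats_family("binomial"), "logit"))
  pi_hat <- predict_relative_abundance(f_bad)
  expect_equal(sum(pi_hat), 1, tolerance = 1e-12)
  expect_gt(max(abs(pi_hat - pr$pi)), 1e-3)
  expect_warning(
    fit_cats(y, NULL, offsets_log(pr), cats_family("binomial"), "logit"),
    "not guaranteed")
})

test_that("fit validation rejects malformed inputs", {
  expect_error(fit_cats(c(1, 2, 3), cbind(rnorm(3), rnorm(3)), NULL,
                        "poisson"), "S > k")
  expect_error(fit_cats(rpois(5, 3), NULL, rep(0, 4), "poisson"),
               "offset length")
  expect_error(fit_cats(c(0.5, 1, 2, 1), NULL, NULL, "poisson"), "support")
  expect_error(fit_cats(rpois(6, 3), NULL, NULL, "negbin", link = "logit"),
               "not supported")
  expect_error(fit_cats(rpois(6, 3) + 1, cbind(rep(1, 6)), NULL,
                        "trunc_poisson"), "standardized")
})
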