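test_that("log-likelihoods match the base-R density oracles", {
  expect_equal(log_likelihood(2, 3, "poisson"), dpois(2, 3, log = TRUE),
               tolerance = 1e-12)
  expect_equal(log_likelihood(2, 3, "poisson"), 2 * log(3) - 3 - log(2),
               tolerance = 1e-12)
  expect_equal(log_likelihood(0, 0 + 1e-300, "gaussian"),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(41)
  y <- rpois(20, 4)
  mu <- runif(20, 0.5, 8)
  expect_equal(log_likelihood(y, mu, "poisson"),
               sum(dpois(y, mu, log = TRUE)), tolerance = 1e-12)
  fam_nb <- cats_family("negbin", theta = 1.7)
  expect_equal(log_likelihood(y, mu, fam_nb),
               sum(dnbinom(y, size = 1.7, mu = mu, log = TRUE)),
               tolerance = 1e-12)
  fam_b <- cats_family("binomial", size = 5)
  yb <- pmin(y, 5)
  mub <- runif(20, 0.5, 4.5)
  expect_equal(log_likelihood(yb, mub, fam_b),
               sum(dbinom(yb, 5, mub / 5, log = TRUE)), tolerance = 1e-12)

  # zero-truncated families against renormalized base densities
  yt <- pmax(y, 1)
  expect_equal(log_likelihood(yt, mu, "trunc_poisson"),
               sum(dpois(yt, mu, log = TRUE) - log(1 - dpois(0, mu))),
               tolerance = 1e-12)
  fam_tnb <- cats_family("trunc_negbin", theta = 1.7)
  expect_equal(log_likelihood(yt, mu, fam_tnb),
               sum(dnbinom(yt, size = 1.7, mu = mu, log = TRUE) -
                     log(1 - dnbinom(0, size = 1.7, mu = mu))),
               tolerance = 1e-12)
})

test_that("negative binomial converges to Poisson as theta grows", {
  y <- c(0, 1, 3, 7, 2)
  mu <- c(0.5, 1.2, 2.5, 6, 2)
  expect_equal(log_likelihood(y, mu, cats_family("negbin", theta = 1e6)),
               log_likelihood(y, mu, "poisson"), tolerance = 1e-3)
})

test_that("Tweedie series density matches an independent evaluation", {
  skip_if_not_installed("mgcv")
  fam <- cats_family("tweedie", p = 1.5, phi = 2)
  y <- c(0, 0.3, 2, 7.5, 40)
  mu <- c(1, 1, 3, 5, 30)
  ours <- vapply(seq_along(y), function(i)
    log_likelihood(y[i], mu[i], fam), numeric(1))
  ref <- vapply(seq_along(y), function(i)
    mgcv::ldTweedie(y[i], mu = mu[i], p = 1.5, phi = 2)[1, 1], numeric(1))
  expect_equal(ours, ref, tolerance = 1e-8)
})

test_that("saturated likelihood uses boundary limits", {
  expect_equal(saturated_loglik(c(0, 0), cats_family("poisson")), 0)
  expect_equal(saturated_loglik(2, cats_family("poisson")),
               dpois(2, 2, log = TRUE), tolerance = 1e-12)
  expect_equal(saturated_loglik(c(1, 0), cats_family("binomial", size = 1)), 0)
  expect_equal(saturated_loglik(c(0, 5), cats_family("negbin", theta = 2)),
               dnbinom(5, size = 2, mu = 5, log = TRUE), tolerance = 1e-12)
  expect_error(saturated_loglik(0, cats_family("trunc_poisson")), "support")
})

test_that("scaled deviance is a likelihood gap and matches closed forms", {
  expect_equal(kl_deviance(2, 3, "poisson"), 2 * (2 * log(2 / 3) + 1),
               tolerance = 1e-12)
  set.seed(42)
  y <- rpois(25, 3)
  mu <- runif(25, 0.5, 6)
  for (fam in list(cats_family("poisson"),
                   cats_family("binomial", size = 8),
                   cats_family("gaussian", sigma2 = 2),
                   cats_family("negbin", theta = 1.3))) {
    yy <- if (fam$name == "binomial") pmin(y, 8) else y
    mm <- if (fam$name == "binomial") pmin(mu, 7.5) else mu
    expect_equal(kl_deviance(yy, mm, fam),
                 sum(unit_deviance(yy, mm, fam)) / catsreg:::family_scale(fam),
                 tolerance = 1e-10, info = fam$name)
    expect_gte(kl_deviance(yy, mm, fam), 0)
    # deviance vanishes as mu -> y (interior points; boundaries use limits)
    yy_int <- if (fam$name == "binomial") pmin(pmax(yy, 1e-8), 8 - 1e-8)
              else if (fam$name == "gaussian") yy else pmax(yy, 1e-10)
    expect_lt(kl_deviance(yy, yy_int, fam), 1e-6)
  }
  # Gaussian deviance is the (scaled) residual sum of squares
  g <- cats_family("gaussian", sigma2 = 1)
  x <- rnorm(10); m <- rnorm(10)
  expect_equal(kl_deviance(x, m, g), sum((x - m)^2), tolerance = 1e-10)
  # Tweedie: series likelihood gap vs closed-form unit deviance
  tw <- cats_family("tweedie", p = 1.4, phi = 0.8)
  yt <- c(0, 0.5, 2, 6)
  mt <- c(1, 1.5, 2.5, 3)
  expect_equal(kl_deviance(yt, mt, tw),
               sum(unit_deviance(yt, mt, tw)) / 0.8, tolerance = 1e-7)
})

test_that("variance functions follow Var(y) = a(phi) b''(psi)", {
  expect_equal(variance_function(4, "poisson"), 4)
  expect_equal(variance_function(4, cats_family("negbin", theta = 1)), 20)
  expect_equal(variance_function(4, cats_family("tweedie", p = 1.5, phi = 2)), 16)
  expect_equal(variance_function(2, cats_family("binomial", size = 8)),
               2 * (1 - 2 / 8))
  expect_equal(variance_function(c(1, 2), cats_family("gaussian", sigma2 = 3)),
               c(3, 3))
})

test_that("truncation adjustment is the exact truncated mean", {
  tp <- cats_family("trunc_poisson")
  expect_equal(truncation_adjust(1, tp), 1 / (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(truncation_adjust(50, tp), 50, tolerance = 1e-6)
  tnb <- cats_family("trunc_negbin", theta = 1)
  expect_equal(truncation_adjust(1, tnb), 2, tolerance = 1e-12)
  for (mu in c(0.05, 0.3, 1, 4)) {
    expect_equal(truncation_adjust(mu, tp), brute_truncated_mean(mu),
                 tolerance = 1e-8)
    expect_equal(truncation_adjust(mu, tnb),
                 brute_truncated_mean(mu, theta = 1), tolerance = 1e-8)
  }
  mus <- c(0.1, 0.5, 1, 2, 5, 20)
  adj <- truncation_adjust(mus, tp)
  expect_true(all(diff(adj) > 0))          # monotone
  expect_true(all(adj > pmax(mus, 1)))     # exceeds both mu and 1
  expect_error(truncation_adjust(1, "poisson"), "zero-truncated")
})

test_that("domain violations are reported with the offending index", {
  expect_error(log_likelihood(c(1, -1), c(1, 1), "poisson"), "observation 2")
  expect_error(log_likelihood(c(1, 2), c(1, -3), "poisson"), "mu\\[2\\]")
  expect_error(log_likelihood(9, 9, cats_family("binomial", size = 8)),
               "outside the support")
  expect_error(log_likelihood(2, 8, cats_family("binomial", size = 8)),
               "mean domain")
  expect_error(check_support(0, cats_family("trunc_poisson")), "support")
})
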