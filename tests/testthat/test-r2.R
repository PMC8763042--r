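test_that("KL R2 endpoints: full model gives 1, null model gives 0", {
  y <- c(1, 2, 3, 0, 5)
  full <- mock_fit(y, pmax(y, 1e-9), "poisson")
  null <- mock_fit(y, rep(mean(y), 5), "poisson")
  expect_equal(r2_kl(full, null)$r2_kl, 1, tolerance = 1e-6)
  expect_equal(r2_kl(null, null)$r2_kl, 0, tolerance = 1e-12)
  expect_error(r2_kl(full, mock_fit(rep(2, 5), rep(2, 5), "poisson")),
               "undefined|different")
})

test_that("Gaussian KL R2 equals the classic least-squares R2", {
  set.seed(31)
  n <- 40
  X <- cbind(rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, -0.5)) + rnorm(n)
  f <- fit_cats(y, X, NULL, "gaussian", "identity")
  ols <- lm(y ~ X)
  r2_classic <- 1 - sum(resid(ols)^2) / sum((y - mean(y))^2)
  expect_equal(r2_kl(f)$r2_kl, r2_classic, tolerance = 1e-10)
})

test_that("deviance and likelihood forms of KL R2 agree across the family matrix", {
  pr <- toy_prior()
  set.seed(32)
  x <- rnorm(10)
  for (fam in list(cats_family("poisson"), cats_family("negbin", theta = 2),
                   cats_family("binomial", size = 6))) {
    mu_true <- if (fam$name == "binomial") rep(3, 10) else 40 * pr$pi
    y <- switch(fam$name,
                poisson = rpois(10, mu_true),
                negbin = rnbinom(10, size = 2, mu = mu_true),
                binomial = rbinom(10, 6, 0.5))
    for (off in list(NULL, offsets_log(pr))) {
      if (fam$name == "binomial" && !is.null(off)) next  # logit + log prior not a fair pair here
      f <- fit_cats(y, x, off, fam)
      nf <- cats_null(f)
      r2 <- r2_kl(f, nf)
      # likelihood-gap form (Eq. 22 shape)
      lsat <- saturated_loglik(y, f$family)
      r2_ll <- (f$loglik - nf$loglik) / (lsat - nf$loglik)
      expect_equal(r2$r2_kl, r2_ll, tolerance = 1e-10, info = fam$name)
      # rescaled likelihood-ratio identity (Eq. 21 shape)
      if (abs(nf$loglik) > 1e-8) {
        expect_equal(r2$r2_likelihood / (1 - lsat / nf$loglik), r2$r2_kl,
                     tolerance = 1e-10, info = fam$name)
      }
    }
  }
})

test_that("Poisson closed form agrees with the generic implementation", {
  set.seed(33)
  for (rep in 1:10) {
    x <- rnorm(15)
    y <- rpois(15, exp(1 + 0.4 * x))
    f <- fit_cats(y, x, NULL, "poisson")
    nf <- cats_null(f)
    expect_equal(r2_poisson_shipley(y, f$mu, nf$mu), r2_kl(f, nf)$r2_kl,
                 tolerance = 1e-10)
  }
  y <- c(1, 2, 3)
  expect_equal(r2_poisson_shipley(y, rep(2, 3), rep(2, 3)), 0)
  expect_equal(r2_poisson_shipley(y, y, rep(2, 3)), 1)
  expect_error(r2_poisson_shipley(c(0.5, 1, 2), rep(1, 3), rep(1, 3)),
               "counts")
})

test_that("offset models can have negative KL R2; the alternative form cannot", {
  pr <- meta_prior(c(8, 5, 4, 3, 2, 2, 1, 1, 1, 1))
  set.seed(34)
  y <- rpois(10, 40 * pr$pi)
  # adversarial prior: reverse the ranking
  bad <- meta_prior(rev(pr$mean_abundance))
  f_bad <- fit_cats(y, NULL, offsets_log(bad), "poisson")
  r2 <- r2_kl(f_bad)
  expect_lt(r2$r2_kl, 0)
  alt <- r2_alternative(f_bad)
  expect_gte(alt, 0)
  expect_lte(alt, 1)
  # Gaussian identity-link, no offset: alternative equals the classic value
  X <- rnorm(10)
  yg <- 1 + 0.8 * X + rnorm(10, 0, 0.4)
  fg <- fit_cats(yg, X, NULL, "gaussian", "identity")
  expect_equal(r2_alternative(fg), r2_kl(fg)$r2_kl, tolerance = 1e-8)
})

test_that("offset-only R2 is zero only under the offset-inclusive null", {
  pr <- toy_prior()
  set.seed(35)
  y <- rpois(10, 50 * pr$pi)
  f <- fit_cats(y, NULL, offsets_log(pr), "poisson")
  r2_incl <- r2_kl(f, convention = "intercept_plus_offset")
  expect_equal(r2_incl$r2_kl, 0, tolerance = 1e-8)
  r2_only <- r2_kl(f, convention = "intercept_only")
  expect_gt(abs(r2_only$r2_kl), 1e-3)
})

test_that("adjusted R2 reduces to Ezekiel for Gaussian fits and to R2 at k = 0", {
  set.seed(36)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  y <- drop(X %*% c(0.8, 0, -0.4)) + rnorm(n)
  f <- fit_cats(y, X, NULL, "gaussian", "identity")
  R2 <- r2_kl(f)$r2_kl
  expect_equal(r2_adjusted(f), 1 - (1 - R2) * (n - 1) / (n - 3 - 1),
               tolerance = 1e-8)
  expect_lte(r2_adjusted(f), R2)
  f0 <- fit_cats(y, NULL, NULL, "gaussian", "identity")
  expect_equal(r2_adjusted(f0, k = 0), r2_kl(f0)$r2_kl, tolerance = 1e-12)
})

test_that("randomization adjustment is seed-reproducible and averages stabilize", {
  sim <- simulate_selection_community(s = 1, seed = 37)
  tm <- matrix(sim$traits)
  off <- offsets_log(sim$prior)
  a <- r2_shipley_adjust(sim$abundance, tm, off, "poisson", n_random = 10,
                         seed = 5)
  b <- r2_shipley_adjust(sim$abundance, tm, off, "poisson", n_random = 10,
                         seed = 5)
  expect_identical(a, b)
  c1 <- r2_shipley_adjust(sim$abundance, tm, off, "poisson", n_random = 1,
                          seed = 6)
  c200 <- r2_shipley_adjust(sim$abundance, tm, off, "poisson",
                            n_random = 200, seed = 6)
  # both estimate the same quantity; the large-n version is stable
  expect_equal(c1, c200, tolerance = 0.1)
  expect_error(r2_shipley_adjust(sim$abundance, NULL, off, "poisson",
                                 n_random = 5, seed = 1), "reshuffle")
})

test_that("variation partition satisfies its component identities", {
  sim <- simulate_selection_community(s = 1.5, seed = 38)
  p <- partition_variation(sim$abundance, sim$traits, sim$prior, "poisson")
  expect_equal(p$pure_trait, p$r2_both - p$r2_offset, tolerance = 1e-12)
  expect_equal(p$pure_meta, p$r2_both - p$r2_traits, tolerance = 1e-12)
  expect_equal(p$joint, p$r2_traits + p$r2_offset - p$r2_both,
               tolerance = 1e-12)
  expect_equal(p$pure_trait + p$pure_meta + p$joint + p$unexplained, 1,
               tolerance = 1e-12)
  praw <- partition_variation(sim$abundance, sim$traits, sim$prior,
                              "poisson", adjusted = FALSE)
  expect_gte(praw$r2_both + 1e-12, p$r2_both)  # adjustment only subtracts
  js <- jsonlite::fromJSON(partition_json(p))
  expect_equal(js$pure_meta, p$pure_meta, tolerance = 1e-12)
  expect_equal(js$S, p$S)
})

test_that("partition shares dispersion from the full model across nested fits", {
  set.seed(39)
  pr <- meta_prior(rgamma(30, 2))
  tr <- rnorm(30)
  y <- rnbinom(30, size = 1, mu = 100 * pr$pi * exp(0.4 * tr))
  p <- partition_variation(y, tr, pr, cats_family("negbin"))
  th <- p$fits$both$family$theta
  expect_true(p$fits$both$theta_estimated)
  for (nm in c("traits", "offset", "null"))
    expect_equal(p$fits[[nm]]$family$theta, th)
})
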