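# Small reusable fixtures, all generated in code.

toy_prior <- function() meta_prior(c(5, 3, 2, 7, 1, 4, 6, 2, 2, 8))

# A light-weight fit object for formula-level R2 tests where the means are
# prescribed rather than estimated.
mock_fit <- function(y, mu, family, k = 0L) {
  family <- catsreg:::as_cats_family(family)
  ll <- log_likelihood(y, mu, family)
  structure(list(y = y, mu = mu, family = family, k = k,
                 loglik = ll,
                 deviance = kl_deviance(y, mu, family),
                 offset = NULL, offset_values = rep(0, length(y)),
                 n = length(y)),
            class = "cats_fit")
}

# Independent truncated-distribution mean by brute-force pmf summation.
brute_truncated_mean <- function(mu, theta = NULL, kmax = 1000L) {
  k <- seq_len(kmax)
  pk <- if (is.null(theta)) dpois(k, mu) else dnbinom(k, size = theta, mu = mu)
  sum(k * pk) / sum(pk)
}
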