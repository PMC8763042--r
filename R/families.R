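#' Exponential-family specifications for abundance models
#'
#' Constructs a family object describing one of the exponential-family
#' distributions used in CATS regression. The family carries its fixed
#' auxiliary parameters: the dispersion `theta` for the (zero-truncated)
#' negative binomial, the power `p` and dispersion `phi` for the Tweedie
#' with \eqn{1 < p < 2}, the trial count `size` for the binomial, and the
#' variance `sigma2` for the Gaussian. The negative binomial and Tweedie
#' distributions belong to the exponential family only when `theta` and `p`
#' are treated as known constants; estimation of `theta` lives in
#' [fit_cats()] / [estimate_theta()], never here.
#'
#' @param name One of `"gaussian"`, `"poisson"`, `"binomial"`, `"negbin"`,
#'   `"tweedie"`, `"trunc_poisson"`, `"trunc_negbin"`.
#' @param theta Positive dispersion of the (truncated) negative binomial.
#'   `NULL` means "to be estimated" by the fitting layer.
#' @param p Tweedie power parameter, strictly between 1 and 2 (compound
#'   Poisson-gamma regime, point mass at zero).
#' @param phi Positive Tweedie dispersion.
#' @param sigma2 Positive Gaussian variance.
#' @param size Binomial trial count (integer, >= 1). `size = 1` is the
#'   Bernoulli / presence-absence case.
#' @return An object of class `"cats_family"`.
#' @examples
#' cats_family("poisson")
#' cats_family("negbin", theta = 1)
#' cats_family("tweedie", p = 1.5, phi = 2)
#' @export
cats_family <- function(name = c("gaussian", "poisson", "binomial", "negbin",
                                 "tweedie", "trunc_poisson", "trunc_negbin"),
                        theta = NULL, p = 1.5, phi = 1, sigma2 = 1, size = 1) {
  name <- match.arg(name)
  if (name %in% c("negbin", "trunc_negbin") && !is.null(theta)) {
    if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) || theta <= 0)
      stop("`theta` must be a single positive number", call. = FALSE)
  }
  if (name == "trunc_negbin" && is.null(theta))
    stop("zero-truncated negative binomial requires a known `theta`", call. = FALSE)
  if (name == "tweedie") {
    if (p <= 1 || p >= 2) stop("Tweedie power `p` must satisfy 1 < p < 2", call. = FALSE)
    if (phi <= 0) stop("Tweedie dispersion `phi` must be positive", call. = FALSE)
  }
  if (name == "gaussian" && sigma2 <= 0)
    stop("`sigma2` must be positive", call. = FALSE)
  if (name == "binomial" && (size < 1 || size != round(size)))
    stop("`size` must be a positive integer", call. = FALSE)
  structure(
    list(name = name, theta = theta, p = p, phi = phi, sigma2 = sigma2,
         size = as.integer(size)),
    class = "cats_family"
  )
}

#' @export
print.cats_family <- function(x, ...) {
  aux <- switch(x$name,
    gaussian = sprintf("sigma2 = %g", x$sigma2),
    binomial = sprintf("size = %d", x$size),
    negbin = ,
    trunc_negbin = if (is.null(x$theta)) "theta to be estimated"
                   else sprintf("theta = %g", x$theta),
    tweedie = sprintf("p = %g, phi = %g", x$p, x$phi),
    "")
  cat("<cats_family> ", x$name, if (nzchar(aux)) paste0(" (", aux, ")"), "\n", sep = "")
  invisible(x)
}

as_cats_family <- function(family, ...) {
  if (inherits(family, "cats_family")) return(family)
  if (is.character(family) && length(family) == 1L) return(cats_family(family, ...))
  stop("`family` must be a cats_family object or a family name", call. = FALSE)
}

is_truncated <- function(family) family$name %in% c("trunc_poisson", "trunc_negbin")
is_count_family <- function(family)
  family$name %in% c("poisson", "negbin", "trunc_poisson", "trunc_negbin")

# a(phi), the exponential-family scale; deviances reported by the package are
# scaled deviances D* (already divided by a(phi))
family_scale <- function(family) {
  switch(family$name,
         gaussian = family$sigma2,
         tweedie = family$phi,
         1)
}

need_theta <- function(family) {
  if (family$name %in% c("negbin", "trunc_negbin") && is.null(family$theta))
    stop("`theta` has not been fixed for this family; fit with estimate_theta()",
         call. = FALSE)
  invisible(family$theta)
}

#' Check that observations lie in the family's support
#'
#' Count families require nonnegative integers, zero-truncated families
#' strictly positive integers, the binomial integers in `0..size`, the
#' Tweedie nonnegative reals. The first offending index is named in the
#' error.
#'
#' @param y Numeric vector of observed abundances.
#' @param family A [cats_family()] object.
#' @return Invisibly `y`, or an error.
#' @export
check_support <- function(y, family) {
  family <- as_cats_family(family)
  if (!is.numeric(y) || anyNA(y)) stop("`y` must be numeric without NA", call. = FALSE)
  bad <- switch(family$name,
    gaussian = rep(FALSE, length(y)),
    poisson = ,
    negbin = y < 0 | y != round(y),
    binomial = y < 0 | y > family$size | y != round(y),
    tweedie = y < 0,
    trunc_poisson = ,
    trunc_negbin = y < 1 | y != round(y))
  if (any(bad))
    stop(sprintf("observation %d (y = %g) is outside the support of the %s family",
                 which(bad)[1L], y[which(bad)[1L]], family$name), call. = FALSE)
  invisible(y)
}

check_mean_domain <- function(mu, family, what = "mu") {
  bad <- switch(family$name,
    gaussian = !is.finite(mu),
    binomial = !is.finite(mu) | mu <= 0 | mu >= family$size,
    !is.finite(mu) | mu <= 0)
  if (any(bad))
    stop(sprintf("%s[%d] = %g is outside the mean domain of the %s family",
                 what, which(bad)[1L], mu[which(bad)[1L]], family$name), call. = FALSE)
  invisible(mu)
}

# log(1 - exp(x)) for x < 0, stable near both ends
log1mexp <- function(x) {
  ifelse(x > -log(2), log(-expm1(x)), log1p(-exp(x)))
}

# ---- per-observation log-density ------------------------------------------
# Written with lgamma() so that non-integer "observations" are permitted;
# this is what makes K(mu; mu0) computable for discrete families.
loglik_terms <- function(y, mu, family) {
  switch(family$name,
    gaussian = {
      -0.5 * log(2 * pi * family$sigma2) - (y - mu)^2 / (2 * family$sigma2)
    },
    poisson = {
      ifelse(y == 0, 0, y * log(mu)) - mu - lgamma(y + 1)
    },
    binomial = {
      n <- family$size
      pr <- mu / n
      lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1) +
        ifelse(y == 0, 0, y * log(pr)) +
        ifelse(y == n, 0, (n - y) * log1p(-pr))
    },
    negbin = {
      th <- need_theta(family)
      lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
        th * (log(th) - log(th + mu)) +
        ifelse(y == 0, 0, y * (log(mu) - log(th + mu)))
    },
    tweedie = {
      ldtweedie_cpg(y, mu, family$p, family$phi)
    },
    trunc_poisson = {
      ifelse(y == 0, 0, y * log(mu)) - mu - lgamma(y + 1) - log1mexp(-mu)
    },
    trunc_negbin = {
      th <- need_theta(family)
      lp0 <- th * (log(th) - log(th + mu))
      lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
        th * (log(th) - log(th + mu)) +
        ifelse(y == 0, 0, y * (log(mu) - log(th + mu))) -
        log1mexp(lp0)
    },
    stop("unknown family"))
}

# Tweedie (1<p<2) log-density via its compound Poisson-gamma representation:
# y = sum of N iid Gamma variables, N ~ Poisson(lambda). The series over N
# peaks near j* = y^(2-p)/(phi(2-p)); it is evaluated by log-sum-exp over a
# window wide enough that the neglected tail is far below the working
# precision (the terms decay super-geometrically in both directions).
ldtweedie_cpg <- function(y, mu, p, phi) {
  lambda <- mu^(2 - p) / (phi * (2 - p))          # Poisson rate
  alpha <- (2 - p) / (p - 1)                       # gamma shape per event
  lbeta_s <- log(phi) + log(p - 1) + (p - 1) * log(mu)  # log gamma scale
  out <- numeric(length(y))
  for (i in seq_along(y)) {
    if (y[i] == 0) { out[i] <- -lambda[i]; next }
    jhat <- max(1, y[i]^(2 - p) / (phi * (2 - p)))
    j <- seq(max(1, floor(jhat - 12 * sqrt(jhat) - 40)),
             ceiling(jhat + 12 * sqrt(jhat) + 40))
    lt <- j * alpha * (log(y[i]) - lbeta_s[i]) - log(y[i]) +
      j * log(lambda[i]) - lgamma(j + 1) - lgamma(j * alpha)
    lmax <- max(lt)
    out[i] <- lmax + log(sum(exp(lt - lmax))) - lambda[i] - y[i] / exp(lbeta_s[i])
  }
  out
}

#' Log-likelihood of abundances under a fitted mean vector
#'
#' Sums the exponential-family log-density
#' \eqn{\log f(y_i; \psi(\mu_i), \phi)} over species, with the canonical
#' parameter obtained from the mean by inverting \eqn{\mu = b'(\psi)}.
#' Non-integer `y` is accepted for the discrete families (the factorials are
#' continued through the gamma function), which is what allows
#' Kullback-Leibler divergences between mean vectors to be computed.
#'
#' @param y Observed abundances (in the family's support; see
#'   [check_support()]).
#' @param mu Mean vector, strictly inside the family's mean domain.
#' @param family A [cats_family()] object.
#' @param check Validate support/domain (set `FALSE` in tight loops).
#' @return A finite scalar log-likelihood.
#' @examples
#' log_likelihood(2, 3, cats_family("poisson"))  # 2*log(3) - 3 - log(2)
#' @export
log_likelihood <- function(y, mu, family, check = TRUE) {
  family <- as_cats_family(family)
  if (length(mu) == 1L) mu <- rep(mu, length(y))
  stopifnot(length(y) == length(mu))
  if (check) {
    check_support(y, family)
    check_mean_domain(mu, family)
  }
  sum(loglik_terms(y, mu, family))
}

#' Saturated (full-model) log-likelihood
#'
#' Log-likelihood of the model whose predictions equal the observations,
#' \eqn{l(\mu^{full}; y)} with \eqn{\mu^{full} = y}. Boundary observations
#' (zero counts, binomial 0 or `size`) use the analytic limit
#' (\eqn{0 \log 0 \equiv 0}), the standard GLM convention that keeps the
#' deviance finite. For zero-truncated families the per-observation supremum
#' is attained where the *truncated* mean equals the observation, so the
#' untruncated mean is recovered with [solve_untruncated_mean()]; at
#' \eqn{y = 1} the supremum is the \eqn{\mu \to 0} limit, which is 0 on the
#' log scale.
#'
#' @inheritParams log_likelihood
#' @return A scalar log-likelihood.
#' @export
saturated_loglik <- function(y, family, check = TRUE) {
  family <- as_cats_family(family)
  if (check) check_support(y, family)
  switch(family$name,
    gaussian = sum(rep(-0.5 * log(2 * pi * family$sigma2), length(y))),
    poisson = sum(ifelse(y == 0, 0, y * log(pmax(y, 1)) - y - lgamma(y + 1))),
    binomial = {
      n <- family$size
      sum(lgamma(n + 1) - lgamma(y + 1) - lgamma(n - y + 1) +
            ifelse(y == 0, 0, y * log(y / n)) +
            ifelse(y == n, 0, (n - y) * log1p(-y / n)))
    },
    negbin = {
      th <- need_theta(family)
      sum(ifelse(y == 0, 0,
                 lgamma(y + th) - lgamma(th) - lgamma(y + 1) +
                   th * (log(th) - log(th + y)) + y * (log(y) - log(th + y))))
    },
    tweedie = {
      pos <- y > 0
      s <- 0
      if (any(pos)) s <- sum(ldtweedie_cpg(y[pos], y[pos], family$p, family$phi))
      s  # y = 0 terms: mu -> 0 gives point mass 1, log 0 contribution
    },
    trunc_poisson = ,
    trunc_negbin = {
      sum(vapply(y, function(yi) {
        if (yi <= 1) return(0)
        mi <- solve_untruncated_mean(yi, family)
        loglik_terms(yi, mi, family)
      }, numeric(1)))
    })
}

#' Scaled deviance (twice the Kullback-Leibler divergence)
#'
#' \eqn{D^*(\mu; y) = 2[l(\mu^{full}; y) - l(\mu; y)]}, the scaled deviance,
#' which equals twice the within-family Kullback-Leibler divergence between
#' the observations and the fitted means. Always nonnegative; zero exactly
#' when `mu == y` elementwise.
#'
#' @inheritParams log_likelihood
#' @return A nonnegative scalar.
#' @examples
#' kl_deviance(2, 3, cats_family("poisson"))  # 2*(2*log(2/3) + 1)
#' @export
kl_deviance <- function(y, mu, family, check = TRUE) {
  family <- as_cats_family(family)
  2 * (saturated_loglik(y, family, check = check) -
         log_likelihood(y, mu, family, check = check))
}

#' Kullback-Leibler divergence between two mean vectors
#'
#' \eqn{K(a; b)}: twice the likelihood gap when data equal to `a` are scored
#' under means `b`, within the given family. Used by the alternative
#' R-squared, where the divergence between fitted and null means is needed.
#' `a` must lie strictly inside the mean domain (and above 1 for the
#' zero-truncated families, where the saturated inverse exists only there).
#'
#' @param a,b Mean vectors of equal length.
#' @inheritParams log_likelihood
#' @return A nonnegative scalar.
#' @export
kl_divergence <- function(a, b, family) {
  family <- as_cats_family(family)
  check_mean_domain(a, family, "a")
  check_mean_domain(b, family, "b")
  if (is_truncated(family) && any(a <= 1))
    stop("KL divergence for truncated families requires means > 1", call. = FALSE)
  2 * (saturated_loglik(a, family, check = FALSE) -
         log_likelihood(a, b, family, check = FALSE))
}

#' Closed-form unit deviances
#'
#' Textbook per-observation deviance contributions (unscaled, i.e. before
#' division by \eqn{a(\phi)}). Provided as an independent route to the same
#' quantity as [kl_deviance()]: the likelihood-gap and closed-form
#' evaluations must agree, which the test suite exploits. Not defined for
#' the zero-truncated families (no closed form).
#'
#' @inheritParams log_likelihood
#' @return Vector of per-observation deviance contributions.
#' @export
unit_deviance <- function(y, mu, family) {
  family <- as_cats_family(family)
  switch(family$name,
    gaussian = (y - mu)^2,
    poisson = 2 * (ifelse(y == 0, 0, y * log(y / mu)) - (y - mu)),
    binomial = {
      n <- family$size
      2 * (ifelse(y == 0, 0, y * log(y / mu)) +
             ifelse(y == n, 0, (n - y) * log((n - y) / (n - mu))))
    },
    negbin = {
      th <- need_theta(family)
      2 * (ifelse(y == 0, 0, y * log(y / mu)) -
             (y + th) * log((y + th) / (mu + th)))
    },
    tweedie = {
      p <- family$p
      2 * (ifelse(y == 0, 0, y^(2 - p) / ((1 - p) * (2 - p))) -
             y * mu^(1 - p) / (1 - p) + mu^(2 - p) / (2 - p))
    },
    stop("no closed-form unit deviance for family ", family$name))
}

#' Variance function
#'
#' \eqn{Var(y) = a(\phi) b''(\psi)} evaluated at the given means:
#' \eqn{\sigma^2} (Gaussian), \eqn{\mu} (Poisson),
#' \eqn{\mu(1 - \mu/n)} (binomial), \eqn{\mu + \mu^2/\theta} (negative
#' binomial), \eqn{\phi \mu^p} (Tweedie). For the zero-truncated families
#' the variance of the *untruncated* parent is returned (the weight used by
#' their estimating equations).
#'
#' @inheritParams log_likelihood
#' @return Vector of variances.
#' @export
variance_function <- function(mu, family) {
  family <- as_cats_family(family)
  check_mean_domain(mu, family)
  switch(family$name,
    gaussian = rep(family$sigma2, length(mu)),
    poisson = ,
    trunc_poisson = mu,
    binomial = mu * (1 - mu / family$size),
    negbin = ,
    trunc_negbin = mu + mu^2 / need_theta(family),
    tweedie = family$phi * mu^family$p)
}

#' Mean of the zero-truncated distribution
#'
#' Expected abundance given presence: \eqn{\mu / (1 - e^{-\mu})} for the
#' truncated Poisson and \eqn{\mu / (1 - ((\mu+\theta)/\theta)^{-\theta})}
#' for the truncated negative binomial, where \eqn{\mu} is the mean of the
#' untruncated parent. Strictly greater than both `mu` and 1, and monotone
#' increasing in `mu`.
#'
#' @param mu Positive untruncated means.
#' @param family A truncated [cats_family()].
#' @return Vector of truncated means.
#' @examples
#' truncation_adjust(1, cats_family("trunc_poisson"))          # 1/(1 - exp(-1))
#' truncation_adjust(1, cats_family("trunc_negbin", theta = 1)) # 2
#' @export
truncation_adjust <- function(mu, family) {
  family <- as_cats_family(family)
  if (!is_truncated(family))
    stop("truncation_adjust() applies only to zero-truncated families", call. = FALSE)
  check_mean_domain(mu, family)
  if (family$name == "trunc_poisson") {
    mu / (-expm1(-mu))
  } else {
    th <- need_theta(family)
    mu / (-expm1(th * (log(th) - log(th + mu))))
  }
}

# ---- cumulative distribution, for randomized quantile residuals -----------
family_cdf <- function(q, mu, family) {
  switch(family$name,
    gaussian = pnorm(q, mean = mu, sd = sqrt(family$sigma2)),
    poisson = ppois(q, lambda = mu),
    binomial = pbinom(q, size = family$size, prob = mu / family$size),
    negbin = pnbinom(q, size = need_theta(family), mu = mu),
    trunc_poisson = {
      f0 <- ppois(0, mu)
      pmax(0, (ppois(q, mu) - f0)) / (1 - f0)
    },
    trunc_negbin = {
      th <- need_theta(family)
      f0 <- pnbinom(0, size = th, mu = mu)
      pmax(0, (pnbinom(q, size = th, mu = mu) - f0)) / (1 - f0)
    },
    tweedie = {
      mapply(function(qi, mi) {
        if (qi < 0) return(0)
        lam <- mi^(2 - family$p) / (family$phi * (2 - family$p))
        mass0 <- exp(-lam)
        if (qi == 0) return(mass0)
        dens <- function(x) exp(ldtweedie_cpg(x, rep(mi, length(x)),
                                              family$p, family$phi))
        mass0 + stats::integrate(dens, 0, qi, rel.tol = 1e-8,
                                 stop.on.error = FALSE)$value
      }, q, mu)
    })
}
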