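ALLOWED_LINKS <- list(
  gaussian = c("identity", "log"),
  poisson = c("log", "identity", "sqrt"),
  binomial = c("logit", "log", "probit", "cloglog"),
  negbin = c("log"),
  tweedie = c("log"),
  trunc_poisson = c("log"),
  trunc_negbin = c("log"))

default_link <- function(family) {
  switch(family$name, gaussian = "identity", binomial = "logit", "log")
}

# Build the design matrix: intercept plus (optionally standardized) traits.
build_design <- function(traits, n, standardize) {
  if (is.null(traits)) {
    return(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                k = 0L, center = NULL, scale = NULL, traits = NULL))
  }
  tm <- as.matrix(traits)
  if (is.null(colnames(tm))) colnames(tm) <- paste0("trait", seq_len(ncol(tm)))
  if (!is.numeric(tm) || anyNA(tm))
    stop("trait matrix must be numeric without missing values", call. = FALSE)
  if (nrow(tm) != n)
    stop("trait matrix has ", nrow(tm), " rows but there are ", n, " species",
         call. = FALSE)
  center <- scale_ <- NULL
  ts <- tm
  if (standardize) {
    center <- colMeans(tm)
    scale_ <- apply(tm, 2, stats::sd)
    if (any(scale_ == 0)) stop("constant trait column cannot be standardized",
                               call. = FALSE)
    ts <- sweep(sweep(tm, 2, center), 2, scale_, "/")
  }
  list(X = cbind(`(Intercept)` = 1, ts), k = ncol(tm),
       center = center, scale = scale_, traits = tm)
}

#' Fit a CATS regression
#'
#' Maximum-likelihood fit of a GLM of local abundance on species traits,
#' optionally carrying the meta-community expectation as an offset on the
#' link scale. The model always contains an intercept (CATS models predict
#' relative, not total, abundance). Gaussian, Poisson, binomial and
#' fixed-`theta` negative binomial fits use iteratively reweighted least
#' squares; the constrained log-binomial, the Tweedie and the
#' zero-truncated count families use dedicated in-package optimizers. A
#' negative binomial family without a fixed `theta` estimates `theta` by
#' alternating profile likelihood (see [estimate_theta()]).
#'
#' @param y Abundance vector (counts, 0/1 or counts up to `size` for the
#'   binomial, nonnegative mass for the Tweedie, positive counts for the
#'   truncated families).
#' @param traits Optional vector/matrix/data.frame of trait predictors
#'   (one row per species). `NULL` fits an intercept-only model.
#' @param offset A [offsets_log()] / [offsets_general()] object or a plain
#'   numeric vector on the link scale; `NULL` for none.
#' @param family A [cats_family()] or family name.
#' @param link Link name; defaults to the family's conventional link
#'   (identity for Gaussian, logit for binomial, log otherwise). The log
#'   link is allowed for every family.
#' @param standardize Center and scale trait columns (default `TRUE`), so
#'   slopes are comparable across plots. Set `FALSE` when slopes must be in
#'   the traits' native units.
#' @param species Optional species identifiers.
#' @return An object of class `"cats_fit"`: coefficients, their standard
#'   errors, fitted means `mu`, `expected_abundance` (equal to `mu` except
#'   for truncated families, where the truncated mean applies), the
#'   log-likelihood, the scaled deviance, and bookkeeping fields.
#' @examples
#' set.seed(1)
#' x <- rnorm(30, 10, 3)
#' y <- rpois(30, exp(0.3 * (x - 10)))
#' fit_cats(y, x, family = "poisson")
#' @export
fit_cats <- function(y, traits = NULL, offset = NULL, family,
                     link = NULL, standardize = TRUE, species = NULL) {
  family <- as_cats_family(family)
  if (is.null(link)) link <- default_link(family)
  if (!link %in% ALLOWED_LINKS[[family$name]])
    stop(sprintf("link '%s' is not supported for the %s family (allowed: %s)",
                 link, family$name,
                 paste(ALLOWED_LINKS[[family$name]], collapse = ", ")),
         call. = FALSE)
  check_support(y, family)
  n <- length(y)
  if (inherits(offset, "cats_offset") && offset$link != link)
    warning(sprintf(paste0("offset was built for the %s link but the model uses ",
                           "the %s link; predicted relative abundances are not ",
                           "guaranteed to reproduce the prior"),
                    offset$link, link), call. = FALSE)
  off <- if (is.null(offset)) rep(0, n) else offset_values(offset, n)
  if (anyNA(off)) stop("offset contains NA (excluded species?); drop those ",
                       "species before fitting", call. = FALSE)
  des <- build_design(traits, n, standardize)
  if (n <= des$k + 1L)
    stop("need more species than parameters (S > k + 1)", call. = FALSE)

  if (family$name %in% c("negbin", "trunc_negbin") && is.null(family$theta))
    return(estimate_theta(y, traits = traits, offset = offset, link = link,
                          standardize = standardize, species = species))

  fit <- if (family$name == "binomial" && link == "log") {
    fit_glm_logbin(y, des$X, off, family)
  } else if (family$name %in% c("gaussian", "poisson", "binomial")) {
    fit_glm_irls(y, des$X, off, family, link)
  } else if (family$name == "negbin") {
    fit_glm_irls(y, des$X, off, family, link)
  } else if (family$name == "tweedie") {
    fit_tweedie_irls(y, des$X, off, family)
  } else {
    fit_truncated_ml(y, des$X, off, family)
  }

  finish_cats_fit(fit, y, des, off, offset, family, link, species)
}

# Shared post-processing: dispersion estimates, likelihood, deviance, SEs.
finish_cats_fit <- function(fit, y, des, off, offset_obj, family, link, species) {
  mu <- fit$mu
  k <- des$k
  n <- length(y)
  if (family$name == "gaussian") {
    # dispersion from the evaluated model's residual df; reused for nested
    # deviances so that the Gaussian adjusted R2 reduces to Ezekiel's formula
    family$sigma2 <- sum((y - mu)^2) / (n - k - 1L)
  }
  if (family$name == "tweedie") {
    family$phi <- sum(unit_deviance(y, mu, cats_family("tweedie", p = family$p,
                                                       phi = 1))) / (n - k - 1L)
  }
  ll <- log_likelihood(y, mu, family, check = FALSE)
  dev <- 2 * (saturated_loglik(y, family, check = FALSE) - ll)
  vc <- fit$vcov
  if (is.null(vc)) {
    lk <- stats::make.link(link)
    eta <- lk$linkfun(if (family$name == "binomial") mu / family$size else mu)
    dmu <- lk$mu.eta(eta)
    if (family$name == "binomial") dmu <- dmu * family$size
    w <- dmu^2 / variance_function(mu, family)
    info <- crossprod(des$X * sqrt(w))
    vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, k + 1, k + 1))
  }
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(fit$coefficients) <- colnames(des$X)
  structure(list(
    coefficients = fit$coefficients, se = se, vcov = vc,
    family = family, link = link,
    mu = as.numeric(mu),
    expected_abundance = if (is_truncated(family))
      as.numeric(truncation_adjust(mu, family)) else as.numeric(mu),
    loglik = ll, deviance = dev,
    offset = offset_obj, offset_values = off,
    k = k, n = n, df_residual = n - k - 1L,
    X = des$X, traits = des$traits,
    trait_center = des$center, trait_scale = des$scale,
    y = y, species = species,
    converged = isTRUE(fit$converged),
    boundary = isTRUE(fit$boundary),
    theta_estimated = isTRUE(fit$theta_estimated)),
    class = "cats_fit")
}

fit_glm_irls <- function(y, X, off, family, link) {
  glmfam <- switch(family$name,
    gaussian = stats::gaussian(link = link),
    poisson = stats::poisson(link = link),
    binomial = stats::binomial(link = link),
    negbin = MASS::negative.binomial(theta = need_theta(family), link = link))
  if (family$name == "binomial") {
    res <- stats::glm.fit(x = X, y = y / family$size,
                          weights = rep(family$size, length(y)),
                          offset = off, family = glmfam,
                          control = stats::glm.control(maxit = 200))
    mu <- res$fitted.values * family$size
  } else {
    start <- NULL
    if (family$name == "negbin") {
      # IRLS from the default start can diverge at small theta with large
      # counts; the Poisson solution is a reliable warm start
      start <- tryCatch(
        stats::glm.fit(x = X, y = y, offset = off,
                       family = stats::poisson(link = link),
                       control = stats::glm.control(maxit = 100))$coefficients,
        error = function(e) NULL)
      if (anyNA(start)) start <- NULL
    }
    res <- tryCatch(
      stats::glm.fit(x = X, y = y, offset = off, family = glmfam,
                     start = start,
                     control = stats::glm.control(maxit = 200)),
      error = function(e) NULL)
    if (family$name == "negbin" && (is.null(res) || !res$converged))
      return(fit_negbin_ml(y, X, off, family,
                           start = if (!is.null(start)) start
                                   else c(log(mean(y) + 0.5) - mean(off),
                                          rep(0, ncol(X) - 1L))))
    if (is.null(res))
      stop("IRLS failed for the ", family$name, " family", call. = FALSE)
    mu <- res$fitted.values
  }
  if (anyNA(res$coefficients))
    stop("collinear design: coefficients not estimable", call. = FALSE)
  if (!res$converged)
    stop("IRLS did not converge after 200 iterations", call. = FALSE)
  if (family$name == "binomial" && any(mu < 1e-10 | mu > family$size - 1e-10))
    warning("fitted binomial probabilities at the boundary (possible separation)",
            call. = FALSE)
  list(coefficients = res$coefficients, mu = mu, converged = res$converged,
       boundary = res$boundary, vcov = NULL)
}

# Direct ML for the fixed-theta negative binomial with log link, used when
# IRLS diverges (small theta with heavy-tailed counts makes the working
# weights explode). BFGS with the analytic score.
fit_negbin_ml <- function(y, X, off, family, start) {
  th <- need_theta(family)
  negll <- function(beta) {
    mu <- exp(drop(X %*% beta) + off)
    if (any(!is.finite(mu))) return(.Machine$double.xmax)
    -sum(loglik_terms(y, mu, family))
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta) + off)
    -drop(crossprod(X, th * (y - mu) / (mu + th)))
  }
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  mu <- exp(drop(X %*% opt$par) + off)
  list(coefficients = opt$par, mu = mu, converged = opt$convergence == 0,
       vcov = NULL)
}

# Tweedie (1<p<2, log link, fixed p): Fisher scoring with variance mu^p.
# phi cancels from the score equations; it is estimated afterwards by the
# mean unscaled deviance.
fit_tweedie_irls <- function(y, X, off, family) {
  p <- family$p
  mu <- (y + mean(y)) / 2
  eta <- log(mu)
  dev_old <- Inf
  converged <- FALSE
  for (it in 1:200) {
    w <- mu^(2 - p)
    z <- (eta - off) + (y - mu) / mu
    beta <- stats::lm.wfit(X, z, w)$coefficients
    eta <- drop(X %*% beta) + off
    mu <- exp(eta)
    dev <- sum(unit_deviance(y, mu, cats_family("tweedie", p = p, phi = 1)))
    if (is.finite(dev) && abs(dev - dev_old) < 1e-12 * (abs(dev) + 0.1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(coefficients = beta, mu = mu, converged = converged, vcov = NULL)
}

# Zero-truncated Poisson / negative binomial, log link, direct ML with
# analytic gradient and BFGS.
fit_truncated_ml <- function(y, X, off, family) {
  th <- if (family$name == "trunc_negbin") need_theta(family) else NULL
  negll <- function(beta) {
    mu <- exp(drop(X %*% beta) + off)
    -sum(loglik_terms(y, mu, family))
  }
  grad <- function(beta) {
    mu <- exp(drop(X %*% beta) + off)
    dl_deta <- if (family$name == "trunc_poisson") {
      y - mu - mu * exp(-mu) / (-expm1(-mu))
    } else {
      p0 <- exp(th * (log(th) - log(th + mu)))
      mu * (y / mu - (y + th) / (mu + th) - p0 * th / ((th + mu) * (1 - p0)))
    }
    -drop(crossprod(X, dl_deta))
  }
  ybar <- mean(y)
  mu0 <- if (ybar > 1 + 1e-8) solve_untruncated_mean(ybar, family) else ybar / 2
  start <- c(log(mu0) - mean(off), rep(0, ncol(X) - 1L))
  opt <- stats::optim(start, negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  H <- stats::optimHess(opt$par, negll, grad)
  vc <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  mu <- exp(drop(X %*% opt$par) + off)
  list(coefficients = opt$par, mu = mu, converged = opt$convergence == 0,
       vcov = vc)
}

# Log-binomial: ML under the constraint eta = X beta + O < 0 (mu < size),
# via constrOptim (adaptive log-barrier on the linear constraints) started
# from a logit fit's mean structure mapped to the log scale.
fit_glm_logbin <- function(y, X, off, family) {
  n_tr <- family$size
  S <- length(y)
  if (all(y == 0) || all(y == n_tr)) {
    warning("degenerate response: log-binomial fit is at the boundary of the ",
            "parameter space and not identifiable", call. = FALSE)
    beta <- c(if (all(y == 0)) -20 else -1e-8, rep(0, ncol(X) - 1L))
    mu <- n_tr * exp(drop(X %*% beta) + off)
    return(list(coefficients = beta, mu = mu, converged = FALSE,
                boundary = TRUE,
                vcov = matrix(NA_real_, ncol(X), ncol(X))))
  }
  negll <- function(beta) {
    eta <- drop(X %*% beta) + off
    if (any(eta >= 0)) return(Inf)
    -sum(y * eta + (n_tr - y) * log1mexp(eta))
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta) + off
    p <- exp(eta)
    -drop(crossprod(X, y - (n_tr - y) * p / (1 - p)))
  }
  # feasible start from the logit fit
  lf <- stats::glm.fit(x = X, y = y / n_tr, weights = rep(n_tr, S),
                       offset = off, family = stats::binomial())
  eta_t <- log(pmin(lf$fitted.values, 0.99))
  beta <- drop(qr.solve(X, eta_t - off))
  excess <- max(drop(X %*% beta) + off)
  if (excess > -1e-6) beta[1L] <- beta[1L] - (excess + 0.05)
  margin <- 1e-9
  opt <- stats::constrOptim(beta, negll, grad, ui = -X, ci = off + margin,
                            method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-14),
                            outer.iterations = 200, outer.eps = 1e-10)
  eta <- drop(X %*% opt$par) + off
  boundary <- max(eta) > -1e-4
  if (boundary)
    warning("log-binomial solution lies on the mean-constraint boundary ",
            "(mu approaching the trial count)", call. = FALSE)
  H <- stats::optimHess(opt$par, negll, grad)
  vc <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(coefficients = opt$par, mu = n_tr * exp(eta),
       converged = opt$convergence == 0, boundary = boundary, vcov = vc)
}

#' Negative binomial CATS fit with estimated dispersion
#'
#' Alternates between an IRLS fit at fixed `theta` and a one-dimensional
#' profile-likelihood update of `theta` at the current means, until the
#' dispersion stabilizes. The `theta` estimated for the evaluated model is
#' stored in the returned fit's family and is the one reused when computing
#' saturated and null likelihoods for R-squared (see [r2_kl()]). When the
#' data carry no overdispersion, `theta` diverges; it is then capped at
#' 1e6 with a "Poisson-like" warning.
#'
#' @inheritParams fit_cats
#' @param max_iter Maximum alternation steps.
#' @return A `"cats_fit"` whose family carries the estimated `theta` and
#'   with `theta_estimated = TRUE`.
#' @export
estimate_theta <- function(y, traits = NULL, offset = NULL, link = "log",
                           standardize = TRUE, species = NULL, max_iter = 50L) {
  check_support(y, cats_family("poisson"))
  if (length(y) < 5L) stop("theta estimation needs at least 5 species", call. = FALSE)
  m <- mean(y)
  v <- stats::var(y)
  th <- if (v > m * (1 + 1e-8)) m^2 / (v - m) else 100
  th <- min(max(th, 1e-3), 1e6)
  capped <- FALSE
  fit <- NULL
  for (it in seq_len(max_iter)) {
    fit <- fit_cats(y, traits = traits, offset = offset,
                    family = cats_family("negbin", theta = th), link = link,
                    standardize = standardize, species = species)
    prof <- stats::optimize(function(lt)
      -sum(loglik_terms(y, fit$mu, cats_family("negbin", theta = exp(lt)))),
      interval = c(log(1e-4), log(1e7)))
    th_new <- exp(prof$minimum)
    if (th_new >= 1e6) {
      th_new <- 1e6
      capped <- TRUE
    }
    done <- abs(log(th_new) - log(th)) < 1e-8
    th <- th_new
    if (done || capped) break
  }
  if (capped)
    warning("estimated theta reached the 1e6 cap: data look Poisson-like ",
            "(no overdispersion to estimate)", call. = FALSE)
  fit <- fit_cats(y, traits = traits, offset = offset,
                  family = cats_family("negbin", theta = th), link = link,
                  standardize = standardize, species = species)
  fit$theta_estimated <- TRUE
  fit
}

#' Constrained log-binomial CATS fit
#'
#' Binomial GLM with a log link (relative-risk regression). Standard IRLS
#' may fail here because the mean constraint \eqn{\mu < n} is active, so
#' the fit maximizes the binomial likelihood under the linear constraints
#' \eqn{\beta_0 + O_i + x_i'\beta < 0} with an adaptive log-barrier,
#' started from a logit fit's mean structure mapped to the log scale.
#' Solutions on the constraint boundary are flagged with a warning.
#'
#' @inheritParams fit_cats
#' @param n_trials Binomial trial count (1 for presence/absence).
#' @return A `"cats_fit"`.
#' @export
fit_log_binomial <- function(y, traits = NULL, offset = NULL, n_trials = 1L,
                             standardize = TRUE, species = NULL) {
  fit_cats(y, traits = traits, offset = offset,
           family = cats_family("binomial", size = n_trials), link = "log",
           standardize = standardize, species = species)
}

#' Two-part (hurdle) CATS fit
#'
#' Fits a binomial model to presence/absence and a zero-truncated count
#' model to the positive abundances, each with its own offset from
#' [hurdle_offsets()]. The combined expected abundance per species is
#' \eqn{P(\mathrm{presence}) \times} the truncated mean of the count part,
#' evaluated for every species (the count-part coefficients are applied to
#' all rows, not only the locally present ones).
#'
#' @inheritParams fit_cats
#' @param offsets A list with elements `binomial` and `truncated` (as
#'   returned by [hurdle_offsets()]), or `NULL` for no offsets.
#' @param family A truncated [cats_family()] (`trunc_poisson` or
#'   `trunc_negbin` with known `theta`) for the count part.
#' @param link_binomial Link for the presence part; defaults to `"log"`
#'   when presence offsets are supplied (they live on the log scale) and
#'   `"logit"` otherwise.
#' @return An object of class `"cats_hurdle"`: the two `"cats_fit"` parts
#'   plus `expected_abundance`.
#' @export
fit_hurdle <- function(y, traits = NULL, offsets = NULL, family,
                       link_binomial = NULL, standardize = TRUE,
                       species = NULL) {
  family <- as_cats_family(family)
  if (!is_truncated(family))
    stop("hurdle count part needs a trunc_poisson or trunc_negbin family",
         call. = FALSE)
  check_support(y, cats_family("poisson"))
  pos <- y > 0
  if (!any(pos)) stop("degenerate hurdle: no positive abundances, the ",
                      "truncated part cannot be fitted", call. = FALSE)
  if (all(pos)) stop("degenerate hurdle: no zeros, the binomial part cannot ",
                     "be fitted", call. = FALSE)
  off_b <- offsets$binomial
  off_t <- offsets$truncated
  if (is.null(link_binomial)) link_binomial <- if (is.null(off_b)) "logit" else "log"
  bin_fit <- fit_cats(as.integer(pos), traits = traits, offset = off_b,
                      family = cats_family("binomial", size = 1L),
                      link = link_binomial, standardize = standardize,
                      species = species)
  tr_traits <- if (is.null(traits)) NULL else as.matrix(traits)[pos, , drop = FALSE]
  off_t_pos <- if (is.null(off_t)) NULL else
    new_offset(offset_values(off_t, length(y))[pos], "log",
               if (is.null(off_t$species)) NULL else off_t$species[pos])
  tr_fit <- fit_cats(y[pos], traits = tr_traits, offset = off_t_pos,
                     family = family, link = "log", standardize = standardize,
                     species = if (is.null(species)) NULL else species[pos])
  mu_all <- predict_mu(tr_fit,
                       newtraits = if (is.null(traits)) NULL else as.matrix(traits),
                       newoffset = if (is.null(off_t)) rep(0, length(y))
                                   else offset_values(off_t, length(y)),
                       n = length(y))
  structure(list(
    binomial = bin_fit, truncated = tr_fit,
    presence_prob = bin_fit$mu,
    expected_abundance = bin_fit$mu * truncation_adjust(mu_all, family),
    y = y, family = family), class = "cats_hurdle")
}

# Evaluate a fit's mean at (possibly new) trait rows and offsets, applying
# the stored standardization.
predict_mu <- function(fit, newtraits = NULL, newoffset = NULL, n = NULL) {
  if (is.null(newtraits) && is.null(newoffset)) return(fit$mu)
  if (is.null(n)) n <- if (!is.null(newtraits)) nrow(as.matrix(newtraits))
                       else length(newoffset)
  if (fit$k > 0L) {
    tm <- as.matrix(newtraits)
    if (!is.null(fit$trait_center))
      tm <- sweep(sweep(tm, 2, fit$trait_center), 2, fit$trait_scale, "/")
    X <- cbind(1, tm)
  } else X <- matrix(1, n, 1)
  off <- if (is.null(newoffset)) rep(0, n) else newoffset
  eta <- drop(X %*% fit$coefficients) + off
  lk <- stats::make.link(fit$link)
  mu <- lk$linkinv(eta)
  if (fit$family$name == "binomial") mu <- mu * fit$family$size
  mu
}

#' Predicted relative abundances
#'
#' Normalizes a fit's expected abundances to sum to one. With an
#' intercept-only model, a log link and log-prior offsets this reproduces
#' the meta-community relative abundances exactly.
#'
#' @param fit A `"cats_fit"` or `"cats_hurdle"`.
#' @return Vector summing to 1.
#' @export
predict_relative_abundance <- function(fit) {
  ea <- fit$expected_abundance
  if (anyNA(ea)) stop("expected abundance contains NA (excluded species)",
                      call. = FALSE)
  ea / sum(ea)
}

#' @export
print.cats_fit <- function(x, ...) {
  cat(sprintf("<cats_fit> %s(%s)%s: S = %d, k = %d\n", x$family$name, x$link,
              if (!is.null(x$offset) || any(x$offset_values != 0))
                " + offset" else "", x$n, x$k))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("logLik %.3f, scaled deviance %.3f%s\n", x$loglik, x$deviance,
              if (x$theta_estimated)
                sprintf(", theta = %.3g (estimated)", x$family$theta) else ""))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.cats_fit <- function(object, ...) object$coefficients

#' @export
vcov.cats_fit <- function(object, ...) object$vcov

#' @export
logLik.cats_fit <- function(object, ...) {
  extra <- switch(object$family$name, gaussian = 1L, tweedie = 1L, 0L) +
    as.integer(isTRUE(object$theta_estimated))
  structure(object$loglik, df = object$k + 1L + extra, nobs = object$n,
            class = "logLik")
}

#' @export
deviance.cats_fit <- function(object, ...) object$deviance

#' @export
confint.cats_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$coefficients - z * object$se,
               object$coefficients + z * object$se)
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
print.cats_hurdle <- function(x, ...) {
  cat("<cats_hurdle> two-part fit\n-- presence part --\n")
  print(x$binomial)
  cat("-- positive-abundance part --\n")
  print(x$truncated)
  invisible(x)
}
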