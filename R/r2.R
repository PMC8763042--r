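#' Intercept-only null fit for R-squared computation
#'
#' Refits the model with no trait predictors, under one of two null
#' conventions. The default, `"intercept_only"`, drops the offset as well:
#' this makes the R-squared of an offset-only model a direct measure of the
#' meta-community effect (and allows it to be negative when the prior
#' worsens the fit). The alternative, `"intercept_plus_offset"`, keeps the
#' offset in the null; under that convention an offset-only model scores
#' exactly zero, which is why it is not the default. Auxiliary parameters
#' estimated in the evaluated model (`theta`, `phi`, `sigma2`) are reused
#' unchanged in the null, so nested deviances are computed on a common
#' likelihood scale.
#'
#' @param fit A `"cats_fit"`.
#' @param convention `"intercept_only"` or `"intercept_plus_offset"`.
#' @return A `"cats_fit"` for the null model.
#' @export
cats_null <- function(fit, convention = c("intercept_only",
                                          "intercept_plus_offset")) {
  convention <- match.arg(convention)
  off <- if (convention == "intercept_plus_offset") {
    if (is.null(fit$offset)) fit$offset_values else fit$offset
  } else NULL
  nf <- suppressWarnings(
    fit_cats(fit$y, traits = NULL, offset = off, family = fit$family,
             link = fit$link, species = fit$species))
  rescore_fit(nf, fit$family)
}

# Recompute loglik/deviance of `fit` under a family with shared auxiliary
# parameters (means are unchanged: dispersion does not enter the mean
# estimating equations for gaussian/tweedie).
rescore_fit <- function(fit, family) {
  fit$family <- family
  fit$loglik <- log_likelihood(fit$y, fit$mu, family, check = FALSE)
  fit$deviance <- 2 * (saturated_loglik(fit$y, family, check = FALSE) - fit$loglik)
  fit
}

check_r2_pair <- function(fit, null_fit) {
  if (!identical(fit$family$name, null_fit$family$name))
    stop("evaluated and null fits use different families", call. = FALSE)
  if (length(fit$y) != length(null_fit$y) || any(fit$y != null_fit$y))
    stop("evaluated and null fits were made on different data", call. = FALSE)
  if (null_fit$deviance <= 0)
    stop("null deviance is zero (constant response): R-squared undefined",
         call. = FALSE)
}

#' Kullback-Leibler R-squared
#'
#' The proportional reduction in Kullback-Leibler divergence between
#' observations and predictions when moving from the null to the evaluated
#' model: \eqn{R^2_{KL} = 1 - K(y;\mu)/K(y;\mu^0)}, computed from scaled
#' deviances. The likelihood-ratio form \eqn{R^2_L = 1 - l(\mu)/l(\mu^0)}
#' is reported alongside; rescaling \eqn{R^2_L} by its maximum recovers
#' \eqn{R^2_{KL}} whenever \eqn{l(\mu^0) \neq 0}.
#'
#' Under the default intercept-only null convention an offset model may fit
#' *worse* than the null, giving a negative value; it is reported, never
#' clipped, and reads as "including the meta-community prior increases the
#' distance between observations and predictions".
#'
#' @param fit Evaluated `"cats_fit"`.
#' @param null_fit Optional null fit sharing `y`, family and auxiliary
#'   parameters; built with [cats_null()] when missing.
#' @param convention Null convention passed to [cats_null()].
#' @return An object of class `"cats_r2"` with fields `r2_kl`,
#'   `r2_adjusted`, `r2_likelihood`, `k`, `null_convention`, `deviance`,
#'   `null_deviance`.
#' @export
r2_kl <- function(fit, null_fit = NULL,
                  convention = c("intercept_only", "intercept_plus_offset")) {
  convention <- match.arg(convention)
  if (is.null(null_fit)) null_fit <- cats_null(fit, convention)
  check_r2_pair(fit, null_fit)
  D <- fit$deviance
  D0 <- null_fit$deviance
  structure(list(
    r2_kl = 1 - D / D0,
    r2_adjusted = (D0 - D - fit$k) / D0,
    r2_likelihood = if (abs(null_fit$loglik) > 0) 1 - fit$loglik / null_fit$loglik
                    else NA_real_,
    method = "kl",
    k = fit$k,
    null_convention = convention,
    deviance = D, null_deviance = D0), class = "cats_r2")
}

#' @export
print.cats_r2 <- function(x, ...) {
  cat(sprintf("KL R2 = %.4f (adjusted %.4f; k = %d, null = %s)\n",
              x$r2_kl, x$r2_adjusted, x$k, x$null_convention))
  invisible(x)
}

#' Deviance-based adjusted Kullback-Leibler R-squared
#'
#' \eqn{R^2_{KL,adj} = [D^*(\mu^0;y) - D^*(\mu;y) - k]\,/\,D^*(\mu^0;y)}.
#' Under trait-free truth the deviance drop from adding `k` unrelated
#' predictors is approximately chi-square with `k` degrees of freedom, so
#' subtracting `k` (its expectation) makes the measure approximately
#' unbiased at zero. `k` counts trait predictors only, never auxiliary
#' parameters. For a Gaussian fit whose variance is estimated from the
#' evaluated model's residuals this reduces exactly to Ezekiel's
#' \eqn{1 - (1 - R^2)(n-1)/(n-k-1)}.
#'
#' @inheritParams r2_kl
#' @param k Number of trait predictors charged; defaults to `fit$k`.
#' @return Scalar adjusted R-squared (at most [r2_kl()]'s value).
#' @export
r2_adjusted <- function(fit, null_fit = NULL, k = fit$k,
                        convention = c("intercept_only",
                                       "intercept_plus_offset")) {
  convention <- match.arg(convention)
  if (is.null(null_fit)) null_fit <- cats_null(fit, convention)
  check_r2_pair(fit, null_fit)
  (null_fit$deviance - fit$deviance - k) / null_fit$deviance
}

#' Alternative R-squared bounded at zero
#'
#' \eqn{R^2 = 1 - K(y;\mu) / [K(y;\mu) + K(\mu;\mu^0)]}, the
#' Kullback-Leibler generalization of the decomposition-based R-squared.
#' Always in \[0, 1\]; for a Gaussian identity-link fit without offset it
#' coincides with the classic formula, and in general it trades the
#' interpretability of a signed distance change for nonnegativity.
#' Requires the fitted means to lie strictly inside the mean domain so the
#' divergence between mean vectors is finite.
#'
#' @inheritParams r2_kl
#' @return Scalar in \[0, 1\].
#' @export
r2_alternative <- function(fit, null_fit = NULL,
                           convention = c("intercept_only",
                                          "intercept_plus_offset")) {
  convention <- match.arg(convention)
  if (is.null(null_fit)) null_fit <- cats_null(fit, convention)
  check_r2_pair(fit, null_fit)
  K_y_mu <- fit$deviance
  K_mu_mu0 <- kl_divergence(fit$mu, null_fit$mu, fit$family)
  1 - K_y_mu / (K_y_mu + K_mu_mu0)
}

#' Closed-form Poisson Kullback-Leibler R-squared
#'
#' The Poisson special case written directly in terms of observed and
#' fitted counts,
#' \eqn{R^2 = 1 - \sum[y \ln(y/\mu) - (y - \mu)] / \sum[y \ln(y/\mu^0) -
#' (y - \mu^0)]} (with \eqn{0 \ln 0 = 0}). Implemented independently of the
#' generic likelihood machinery; the two must agree to numerical precision,
#' which the test suite asserts.
#'
#' @param y Observed counts.
#' @param mu Fitted means of the evaluated model.
#' @param mu0 Fitted means of the null model.
#' @return Scalar R-squared.
#' @export
r2_poisson_shipley <- function(y, mu, mu0) {
  if (any(y < 0 | y != round(y))) stop("`y` must be nonnegative counts",
                                       call. = FALSE)
  if (length(mu0) == 1L) mu0 <- rep(mu0, length(y))
  half_dev <- function(m) sum(ifelse(y == 0, 0, y * log(y / m)) - (y - m))
  1 - half_dev(mu) / half_dev(mu0)
}

#' Randomization-adjusted pure meta-community effect
#'
#' The permutation-based estimate
#' \eqn{[R^2(\mathrm{traits};\mathrm{offset}) - R^2(\mathrm{traits})] /
#' [1 - \overline{R^2(\mathrm{random\ traits})}]}: the numerator is the raw
#' gain from adding the offset to the trait model, and the denominator
#' rescales by the expected unexplained share under reshuffled (effect-free)
#' traits. Trait-matrix *rows* are permuted jointly, preserving the
#' covariance among traits. All R-squared values use the intercept-only
#' null by default.
#'
#' @param y Abundance vector.
#' @param traits Trait matrix (k >= 1 columns).
#' @param offset Offset object or numeric vector (log-prior offsets for a
#'   log link).
#' @param family,link Passed to [fit_cats()].
#' @param n_random Number of trait permutations (>= 1).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param convention Null convention for all R-squared values.
#' @return Scalar pure meta-community component.
#' @export
r2_shipley_adjust <- function(y, traits, offset, family, link = "log",
                              n_random = 99L, seed = 1L,
                              convention = c("intercept_only",
                                             "intercept_plus_offset")) {
  convention <- match.arg(convention)
  comp <- shipley_components(y, traits, offset, family, link = link,
                             n_random = n_random, seed = seed,
                             convention = convention)
  comp$pure_meta
}

#' Randomization-adjusted variation components
#'
#' Reconstruction of the permutation-based partitioning: the pure
#' meta-community component as in [r2_shipley_adjust()], and the symmetric
#' pure-trait component
#' \eqn{[R^2(t;o) - R^2(o)] / [1 - \overline{R^2(\mathrm{random}\ t)}]}.
#' Both components share the same rescaling denominator, the mean
#' R-squared of models with reshuffled (effect-free) traits and no offset.
#' Used to cross-check the deterministic, chi-square-adjusted partition of
#' [partition_variation()]; the two routes should agree closely.
#'
#' @inheritParams r2_shipley_adjust
#' @return List with `pure_meta`, `pure_trait`, `r2_both`, `r2_traits`,
#'   `r2_offset`, `mean_r2_random`.
#' @export
shipley_components <- function(y, traits, offset, family, link = "log",
                               n_random = 99L, seed = 1L,
                               convention = c("intercept_only",
                                              "intercept_plus_offset")) {
  convention <- match.arg(convention)
  if (is.null(traits)) stop("nothing to reshuffle: supply a trait matrix",
                            call. = FALSE)
  n_random <- as.integer(n_random)
  if (n_random < 1L) stop("`n_random` must be at least 1", call. = FALSE)
  seed <- check_seed(seed)
  tm <- as.matrix(traits)
  family <- as_cats_family(family)

  fit_to <- fit_cats(y, tm, offset, family, link)
  family <- fit_to$family  # aux estimated in the most complex model, reused
  null0 <- cats_null(fit_to, "intercept_only")
  fit_t <- rescore_fit(fit_cats(y, tm, NULL, family, link), family)
  fit_o <- rescore_fit(
    suppressWarnings(fit_cats(y, NULL, offset, family, link)), family)

  r2_of <- function(f, nf) 1 - f$deviance / nf$deviance
  r2_to <- if (convention == "intercept_only") r2_of(fit_to, null0)
           else r2_of(fit_to, cats_null(fit_to, "intercept_plus_offset"))
  r2_t <- r2_of(fit_t, null0)
  r2_o <- r2_of(fit_o, null0)

  perms <- with_seed(seed, replicate(n_random, sample.int(nrow(tm)),
                                     simplify = FALSE))
  r2_rand <- vapply(perms, function(p) {
    r2_of(rescore_fit(fit_cats(y, tm[p, , drop = FALSE], NULL, family, link),
                      family), null0)
  }, numeric(1))

  list(pure_meta = (r2_to - r2_t) / (1 - mean(r2_rand)),
       pure_trait = (r2_to - r2_o) / (1 - mean(r2_rand)),
       r2_both = r2_to, r2_traits = r2_t, r2_offset = r2_o,
       mean_r2_random = mean(r2_rand))
}

#' Partition explained variation into trait and meta-community components
#'
#' Fits three models -- traits plus offset, traits only, offset only --
#' against a common intercept-only null and decomposes explained variation:
#' pure trait effect \eqn{R^2(t;o) - R^2(o)}, pure meta-community effect
#' \eqn{R^2(t;o) - R^2(t)}, joint effect \eqn{R^2(t) + R^2(o) - R^2(t;o)},
#' and unexplained \eqn{1 - R^2(t;o)}; the four sum to one. With
#' `adjusted = TRUE` (default) each R-squared is first adjusted by its own
#' predictor count (`k` for models containing traits, 0 for the offset-only
#' model) via [r2_adjusted()], and the components are differences of the
#' adjusted values. Raw (possibly negative) components are reported as is.
#'
#' Auxiliary parameters estimated in the traits+offset model (`theta`,
#' `phi`, `sigma2`) are reused for all nested fits so that deviances share
#' one likelihood scale.
#'
#' @param y Abundance vector.
#' @param traits Trait matrix.
#' @param prior A [meta_prior()]; the offset is built with [offsets_log()]
#'   for the log link and [offsets_general()] otherwise (with
#'   `y_tot = sum(y)`).
#' @param family,link Passed to [fit_cats()].
#' @param adjusted Use the deviance-based adjustment (default `TRUE`).
#' @param standardize Passed to [fit_cats()].
#' @param fallback Passed to [offsets_general()] for non-log links.
#' @return An object of class `"cats_partition"`.
#' @export
partition_variation <- function(y, traits, prior, family, link = "log",
                                adjusted = TRUE, standardize = TRUE,
                                fallback = "error") {
  stopifnot(inherits(prior, "meta_prior"))
  family <- as_cats_family(family)
  offset <- if (link == "log") offsets_log(prior)
            else offsets_general(prior, y_tot = sum(y), link = link,
                                 fallback = fallback)
  fit_both <- tryCatch(
    fit_cats(y, traits, offset, family, link, standardize = standardize),
    error = function(e) stop("traits+offset model failed: ",
                             conditionMessage(e), call. = FALSE))
  family <- fit_both$family
  null0 <- cats_null(fit_both, "intercept_only")
  fit_traits <- tryCatch(
    rescore_fit(fit_cats(y, traits, NULL, family, link,
                         standardize = standardize), family),
    error = function(e) stop("traits-only model failed: ",
                             conditionMessage(e), call. = FALSE))
  fit_offset <- tryCatch(
    rescore_fit(suppressWarnings(fit_cats(y, NULL, offset, family, link)),
                family),
    error = function(e) stop("offset-only model failed: ",
                             conditionMessage(e), call. = FALSE))

  D0 <- null0$deviance
  if (D0 <= 0) stop("null deviance is zero: partition undefined", call. = FALSE)
  k <- fit_both$k
  r2 <- function(fit, kk) {
    if (adjusted) (D0 - fit$deviance - kk) / D0 else 1 - fit$deviance / D0
  }
  r2_both <- r2(fit_both, k)
  r2_traits <- r2(fit_traits, k)
  r2_offset <- r2(fit_offset, 0L)
  structure(list(
    r2_both = r2_both, r2_traits = r2_traits, r2_offset = r2_offset,
    pure_trait = r2_both - r2_offset,
    pure_meta = r2_both - r2_traits,
    joint = r2_traits + r2_offset - r2_both,
    unexplained = 1 - r2_both,
    adjusted = adjusted, family = family$name, link = link,
    k = k, S = length(y),
    fits = list(both = fit_both, traits = fit_traits, offset = fit_offset,
                null = null0)), class = "cats_partition")
}

#' @export
print.cats_partition <- function(x, ...) {
  cat(sprintf("<cats_partition> %s(%s), S = %d, k = %d, %s R2\n",
              x$family, x$link, x$S, x$k,
              if (x$adjusted) "adjusted" else "raw"))
  v <- c(`pure trait` = x$pure_trait, `pure meta-community` = x$pure_meta,
         joint = x$joint, unexplained = x$unexplained)
  print(round(v, 4))
  cat(sprintf("R2: both %.4f, traits %.4f, offset %.4f\n",
              x$r2_both, x$r2_traits, x$r2_offset))
  invisible(x)
}

#' Serialize a variation partition to JSON
#'
#' @param x A `"cats_partition"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
partition_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "cats_partition"))
  payload <- x[c("r2_both", "r2_traits", "r2_offset", "pure_trait",
                 "pure_meta", "joint", "unexplained", "adjusted", "family",
                 "link", "k", "S")]
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
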