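#' Simulate overdispersed single-plot communities
#'
#' Generates replicate plots in which species abundances follow a negative
#' binomial distribution whose mean is log-linear in a single trait:
#' \eqn{y_i \sim \mathrm{NegBin}(\mu_i = e^{s x_i}, \theta)} with
#' \eqn{x_i \sim N(\mathrm{trait\_mean}, \mathrm{trait\_sd})}. The defaults
#' (50 plots of 20 species, slope 0.5, \eqn{\theta = 1}, traits
#' \eqn{N(10, 3)}) are the study conditions used throughout the package's
#' evaluation of slope recovery and overdispersion diagnostics; traits are
#' drawn fresh for every plot.
#'
#' @param n_plots Number of replicate plots.
#' @param n_species Species per plot (>= 2).
#' @param slope Selection strength on the log scale.
#' @param theta Negative binomial dispersion (> 0).
#' @param trait_mean,trait_sd Trait distribution parameters.
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List of `n_plots` data frames with columns `trait`, `abundance`,
#'   and attribute `mu` (the generating means).
#' @export
simulate_overdispersed_plots <- function(n_plots = 50L, n_species = 20L,
                                         slope = 0.5, theta = 1,
                                         trait_mean = 10, trait_sd = 3,
                                         seed) {
  seed <- check_seed(seed)
  if (n_species < 2L) stop("`n_species` must be at least 2", call. = FALSE)
  if (theta <= 0) stop("`theta` must be positive", call. = FALSE)
  if (trait_sd <= 0) stop("`trait_sd` must be positive", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_plots), function(i) {
      x <- stats::rnorm(n_species, trait_mean, trait_sd)
      mu <- exp(slope * x)
      y <- stats::rnbinom(n_species, size = theta, mu = mu)
      out <- data.frame(trait = x, abundance = y)
      attr(out, "mu") <- mu
      out
    })
  })
}

#' Simulate a community assembled by trait selection on a prior
#'
#' Draws one community of `n_species` species from
#' \eqn{y_i \sim \mathrm{Poisson}(\lambda_i)} with
#' \eqn{\log \lambda_i = a + \log \pi_i + s t_i}, where \eqn{\pi} is the
#' meta-community prior, `s` the strength of selection and `t` the traits.
#' The intercept is set to
#' \eqn{a = \log A - \log \sum_i \pi_i e^{s t_i}}, which makes the expected
#' community size exactly \eqn{\sum_i \lambda_i = A} for any `s` -- the
#' selection strength redistributes expected abundance without changing the
#' total. By default the prior is a flat Dirichlet draw over the species
#' pool and traits are standard normal.
#'
#' @param n_species Species-pool size (default 50).
#' @param total_abundance Expected community size \eqn{A} (default 2500).
#' @param s Strength of selection (0 = purely neutral assembly).
#' @param prior Optional [meta_prior()]; drawn flat-Dirichlet when `NULL`.
#' @param traits Optional trait vector; standard normal when `NULL`.
#' @param seed Integer seed.
#' @return List with `abundance`, `lambda` (generating means), `prior`,
#'   `traits`, `intercept`.
#' @export
simulate_selection_community <- function(n_species = 50L,
                                         total_abundance = 2500,
                                         s = 0, prior = NULL, traits = NULL,
                                         seed) {
  seed <- check_seed(seed)
  if (n_species < 2L) stop("`n_species` must be at least 2", call. = FALSE)
  if (total_abundance <= 0) stop("`total_abundance` must be positive",
                                 call. = FALSE)
  with_seed(seed, {
    if (is.null(prior)) {
      w <- stats::rgamma(n_species, shape = 1)  # flat Dirichlet
      prior <- meta_prior(w)
    }
    stopifnot(inherits(prior, "meta_prior"), length(prior$pi) == n_species)
    if (is.null(traits)) traits <- stats::rnorm(n_species)
    stopifnot(length(traits) == n_species)
    a <- log(total_abundance) - log(sum(prior$pi * exp(s * traits)))
    lambda <- exp(a + log(prior$pi) + s * traits)
    y <- stats::rpois(n_species, lambda)
    list(abundance = y, lambda = lambda, prior = prior, traits = traits,
         intercept = a)
  })
}

#' Synthetic presence/absence site-by-species fixture
#'
#' Generates a binary site-by-species matrix with right-skewed species
#' occupancies (Beta-distributed occupancy probabilities), mimicking the
#' structure of a regional presence/absence survey: many rare species, a
#' few widespread ones. With the default dimensions (97 species, 52 sites)
#' some widespread species at species-rich sites violate
#' \eqn{\pi_i y_{tot} < 1}, exercising the logit-link offset domain failure
#' that motivates the log-link recommendation. This is a synthetic
#' stand-in, not a real survey.
#'
#' @param n_species,n_sites Matrix dimensions (each >= 2).
#' @param seed Integer seed.
#' @return List with `matrix` (sites x species, 0/1), `occupancy` (species
#'   occurrence counts across sites), `prior` (a [meta_prior()] over the
#'   occurrence counts).
#' @export
simulate_presence_absence <- function(n_species = 97L, n_sites = 52L, seed) {
  seed <- check_seed(seed)
  stopifnot(n_species >= 2L, n_sites >= 2L)
  with_seed(seed, {
    repeat {
      p_occ <- stats::rbeta(n_species, 0.6, 1.6)
      m <- matrix(stats::rbinom(n_sites * n_species, 1, rep(p_occ, each = n_sites)),
                  nrow = n_sites, ncol = n_species,
                  dimnames = list(paste0("site", seq_len(n_sites)),
                                  paste0("sp", seq_len(n_species))))
      occ <- colSums(m)
      if (all(occ > 0) && all(rowSums(m) > 0)) break
    }
    list(matrix = m, occupancy = occ, prior = meta_prior(occ, colnames(m)))
  })
}
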