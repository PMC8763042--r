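#' Meta-community prior
#'
#' Turns mean abundances of species in the plots representing the
#' meta-community into the relative abundances expected a priori,
#' \eqn{\pi_i = \bar m_i / \sum \bar m_i}. Species with zero mean abundance
#' are retained but flagged: the model cannot represent structural absence
#' in the prior, and downstream offset construction either errors on them or
#' drops them explicitly (see [prune_prior()]), never silently assigns
#' \eqn{-\infty}.
#'
#' @param mean_abundance Nonnegative vector (length >= 2), not all zero.
#' @param species Optional character identifiers, aligned to
#'   `mean_abundance`.
#' @return An object of class `"meta_prior"` with elements `mean_abundance`,
#'   `pi`, `species` and `zero` (logical flags).
#' @examples
#' meta_prior(c(2, 3, 5))$pi  # 0.2 0.3 0.5
#' @export
meta_prior <- function(mean_abundance, species = NULL) {
  if (!is.numeric(mean_abundance) || length(mean_abundance) < 2L)
    stop("`mean_abundance` must be a numeric vector of length >= 2", call. = FALSE)
  if (anyNA(mean_abundance) || any(mean_abundance < 0))
    stop("`mean_abundance` must be nonnegative without NA", call. = FALSE)
  tot <- sum(mean_abundance)
  if (tot <= 0)
    stop("degenerate prior: all meta-community mean abundances are zero", call. = FALSE)
  if (is.null(species)) species <- paste0("sp", seq_along(mean_abundance))
  if (anyDuplicated(species))
    stop("duplicated species identifiers in the prior", call. = FALSE)
  structure(
    list(mean_abundance = as.numeric(mean_abundance),
         pi = as.numeric(mean_abundance) / tot,
         species = as.character(species),
         zero = mean_abundance == 0),
    class = "meta_prior")
}

#' @export
print.meta_prior <- function(x, ...) {
  cat("<meta_prior> ", length(x$pi), " species",
      if (any(x$zero)) sprintf(", %d with zero prior abundance", sum(x$zero)),
      "\n", sep = "")
  invisible(x)
}

#' Drop zero-prior species from a meta-community prior
#'
#' @param prior A [meta_prior()].
#' @return A pruned `meta_prior`, with a warning naming the dropped species.
#' @export
prune_prior <- function(prior) {
  stopifnot(inherits(prior, "meta_prior"))
  if (!any(prior$zero)) return(prior)
  warning("excluding species with zero prior abundance: ",
          paste(prior$species[prior$zero], collapse = ", "), call. = FALSE)
  meta_prior(prior$mean_abundance[!prior$zero], prior$species[!prior$zero])
}

new_offset <- function(values, link, species = NULL) {
  structure(list(values = as.numeric(values), link = link,
                 species = species), class = "cats_offset")
}

#' @export
print.cats_offset <- function(x, ...) {
  cat("<cats_offset> ", length(x$values), " species, built for ",
      x$link, " link\n", sep = "")
  invisible(x)
}

offset_values <- function(offset, n = NULL) {
  v <- if (inherits(offset, "cats_offset")) offset$values else as.numeric(offset)
  if (!is.null(n) && length(v) != n)
    stop("offset length (", length(v), ") does not match the number of species (",
         n, ")", call. = FALSE)
  v
}

#' Log-link offsets from a meta-community prior
#'
#' The classical CATS offset \eqn{O_i = \ln \pi_i}. Because only ratios of
#' the prior relative abundances matter (any constant added to all offsets
#' is absorbed by the intercept), \eqn{\ln \bar m_i} is an equally valid
#' choice; this function uses \eqn{\ln \pi_i}.
#'
#' @param prior A [meta_prior()] with strictly positive relative abundances
#'   (use [prune_prior()] first if needed).
#' @return A `"cats_offset"` built for the log link.
#' @examples
#' offsets_log(meta_prior(c(0.5, 0.3, 0.2)))
#' @export
offsets_log <- function(prior) {
  stopifnot(inherits(prior, "meta_prior"))
  if (any(prior$zero))
    stop("zero prior relative abundance for species: ",
         paste(prior$species[prior$zero], collapse = ", "),
         "; use prune_prior() to drop them explicitly", call. = FALSE)
  new_offset(log(prior$pi), "log", prior$species)
}

#' Offsets for an arbitrary link function
#'
#' General offset construction \eqn{O_i = h(\pi_i y_{tot}) - h(\pi_1
#' y_{tot}) + O_1}: with the default \eqn{O_1 = h(\pi_1 y_{tot})} this is
#' simply \eqn{O_i = h(\pi_i y_{tot})}, so an intercept-only fit with these
#' offsets reproduces \eqn{\mu_i = \pi_i y_{tot}} (up to the intercept).
#' For the log link this reduces to [offsets_log()] plus \eqn{\ln y_{tot}}.
#'
#' The construction requires every \eqn{\pi_i y_{tot}} to be inside the
#' link's domain; for the logit link this means \eqn{\pi_i y_{tot} < 1}.
#' When that fails, `fallback = "log-prior"` substitutes \eqn{\ln \pi_i} as
#' the offset with a warning: predicted relative abundances are then only
#' guaranteed to match the prior under a log link, and with other links they
#' depart from the 1:1 line nonlinearly.
#'
#' @param prior A [meta_prior()] (strictly positive).
#' @param y_tot Positive total abundance of the local community.
#' @param link Link name understood by [stats::make.link()] (e.g. `"log"`,
#'   `"identity"`, `"logit"`).
#' @param O1 Offset assigned to the first species; default
#'   \eqn{h(\pi_1 y_{tot})}, which removes the arbitrary constant.
#' @param fallback `"error"` (default) or `"log-prior"`.
#' @return A `"cats_offset"` for `link`.
#' @examples
#' offsets_general(meta_prior(c(0.2, 0.8)), y_tot = 5, link = "log")
#' @export
offsets_general <- function(prior, y_tot, link = "log", O1 = NULL,
                            fallback = c("error", "log-prior")) {
  stopifnot(inherits(prior, "meta_prior"))
  fallback <- match.arg(fallback)
  if (!is.numeric(y_tot) || length(y_tot) != 1L || y_tot <= 0)
    stop("`y_tot` must be a single positive number", call. = FALSE)
  if (any(prior$zero))
    stop("zero prior relative abundance for species: ",
         paste(prior$species[prior$zero], collapse = ", "), call. = FALSE)
  lk <- stats::make.link(link)
  m <- prior$pi * y_tot
  viol <- if (link %in% c("logit", "probit", "cloglog", "cauchit")) m >= 1
          else rep(FALSE, length(m))
  if (any(viol)) {
    if (fallback == "error") {
      cond <- structure(
        class = c("catsreg_domain_error", "error", "condition"),
        list(message = sprintf(
               "pi * y_tot is outside the %s link domain for %d species (%s)",
               link, sum(viol),
               paste(utils::head(prior$species[viol], 5L), collapse = ", ")),
             call = NULL,
             species = prior$species[viol], n_violations = sum(viol)))
      stop(cond)
    }
    warning("pi * y_tot >= 1 for ", sum(viol), " species; falling back to ",
            "log-prior offsets, for which the prior is reproduced only ",
            "under a log link", call. = FALSE)
    return(new_offset(log(prior$pi), link, prior$species))
  }
  h <- lk$linkfun
  O <- if (is.null(O1)) h(m) else h(m) - h(m[1L]) + O1
  if (any(!is.finite(O)))
    stop("non-finite offset produced; check the prior and link domain", call. = FALSE)
  new_offset(O, link, prior$species)
}

#' Invert the zero-truncation mean adjustment
#'
#' Given the mean abundance of a species *when present*
#' (\eqn{\bar m^+ > 1}), finds the untruncated mean \eqn{\tilde m} such that
#' the zero-truncated distribution with parent mean \eqn{\tilde m} has mean
#' \eqn{\bar m^+}; i.e. the exact inverse of [truncation_adjust()]. The
#' truncated mean always exceeds 1, so inputs at or below 1 are infeasible.
#' Solved by bracketed root search (the map is strictly monotone).
#'
#' @param mean_when_present Scalar or vector of truncated means, each > 1.
#' @param family A truncated [cats_family()] (with known `theta` for the
#'   negative binomial).
#' @param tol Absolute root tolerance.
#' @return \eqn{\tilde m}, same length as the input.
#' @examples
#' solve_untruncated_mean(1 / (1 - exp(-1)), cats_family("trunc_poisson"))  # ~1
#' @export
solve_untruncated_mean <- function(mean_when_present, family, tol = 1e-10) {
  family <- as_cats_family(family)
  if (!is_truncated(family))
    stop("family must be trunc_poisson or trunc_negbin", call. = FALSE)
  vapply(mean_when_present, function(target) {
    if (!is.finite(target) || target <= 1)
      stop("mean-when-present must exceed 1 (the truncated mean's lower ",
           "limit); got ", target, call. = FALSE)
    f <- function(m) truncation_adjust(m, family) - target
    upper <- target  # truncated mean at m = target already exceeds target
    stats::uniroot(f, lower = 1e-12, upper = upper, tol = tol)$root
  }, numeric(1))
}

#' Offsets for a two-part (hurdle) model
#'
#' A hurdle model is fitted as two separate GLMs: a binomial model for
#' presence/absence and a zero-truncated count model for positive
#' abundances. Its meta-community expectation therefore splits into two
#' offsets: the presence part uses the log relative presence frequencies
#' (the standard log-prior offset computed from binary data), and the
#' truncated part uses \eqn{\ln \tilde m_i}, where \eqn{\tilde m_i} is the
#' untruncated mean recovered from the meta-community mean-when-present via
#' [solve_untruncated_mean()].
#'
#' Species never present in the meta-community (`presence_fraction` 0)
#' cannot inform either part; they are excluded with a warning and carry
#' `NA` offsets.
#'
#' @param presence_fraction Vector in \[0, 1\]: fraction of meta-community
#'   plots where each species is present.
#' @param mean_when_present Mean abundance over plots where present; must
#'   exceed 1 wherever the species is ever present.
#' @param family A truncated [cats_family()] for the count part.
#' @param species Optional identifiers.
#' @return List with `"cats_offset"` elements `binomial` and `truncated`,
#'   and `excluded` (indices of never-present species).
#' @export
hurdle_offsets <- function(presence_fraction, mean_when_present, family,
                           species = NULL) {
  family <- as_cats_family(family)
  if (!is_truncated(family))
    stop("hurdle offsets need a truncated count family", call. = FALSE)
  stopifnot(length(presence_fraction) == length(mean_when_present))
  if (any(presence_fraction < 0 | presence_fraction > 1))
    stop("`presence_fraction` must lie in [0, 1]", call. = FALSE)
  if (is.null(species)) species <- paste0("sp", seq_along(presence_fraction))
  excluded <- which(presence_fraction == 0)
  if (length(excluded))
    warning("species never present in the meta-community excluded from both ",
            "hurdle parts: ", paste(species[excluded], collapse = ", "),
            call. = FALSE)
  keep <- presence_fraction > 0
  O_bin <- rep(NA_real_, length(presence_fraction))
  O_bin[keep] <- log(presence_fraction[keep] / sum(presence_fraction[keep]))
  O_tr <- rep(NA_real_, length(presence_fraction))
  O_tr[keep] <- log(solve_untruncated_mean(mean_when_present[keep], family))
  list(binomial = new_offset(O_bin, "log", species),
       truncated = new_offset(O_tr, "log", species),
       excluded = excluded)
}
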