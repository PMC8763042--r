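---
title: "Generalized CATS regression: models, offsets, and variation partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized CATS regression: models, offsets, and variation partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catsreg)
```

## The model

Community assembly by trait selection (CATS) asks how much of the variation
in species' local abundances is attributable to local selection on traits,
and how much to meta-community processes (mass effects, dispersal
limitation). `catsreg` answers this with generalized linear models of the
form

$$ h(\mu_i) \;=\; \beta_0 + \mathbf{x}_i'\boldsymbol\beta + O_i, $$

where $\mu_i$ is species $i$'s expected local abundance, $\mathbf{x}_i$ its
traits, $h$ a link function, and $O_i$ a fixed offset carrying the
*abundance expected a priori* — the species' relative abundance $\pi_i$ in
the plots representing the meta-community, before local conditions are
known. The model always includes an intercept: CATS predicts relative, not
total, abundance, so an intercept-plus-offset model must satisfy
$\hat y_i / \sum_j \hat y_j = \pi_i$.

Abundance is measured in many currencies, and the distributional family
should follow the currency:

| family | currency | auxiliary parameters |
|---|---|---|
| `poisson` | individual counts, random spatial pattern | — |
| `negbin` | overdispersed counts (aggregation) | dispersion $\theta$ |
| `binomial` | presence/absence, frequency in subplots | trials $n$ |
| `gaussian` | symmetric continuous measures | variance $\sigma^2$ |
| `tweedie` ($1<p<2$) | biomass with exact zeros | power $p$, dispersion $\phi$ |
| `trunc_poisson`, `trunc_negbin` | positive counts in hurdle models | ($\theta$) |

All are exponential families *given* their auxiliary parameters; `catsreg`
treats $\theta$ and $p$ as fixed inside the likelihood layer and estimates
$\theta$ (when requested) by alternating profile likelihood in the fitting
layer. The Tweedie power $p$ is never estimated (default 1.5); the Tweedie
is fitted with a log link only.

## Offsets for arbitrary links

With a log link, $O_i = \ln \pi_i$ works because the link turns the
multiplicative prior into an additive constant; any constant shift of all
offsets is absorbed by the intercept, so $\ln \bar m_i$ (raw mean
abundances) is equally valid. With any other link the correct construction
is

$$ O_i = h(\pi_i\, y_{tot}) - h(\pi_1\, y_{tot}) + O_1, $$

implemented by `offsets_general()` with the convention
$O_1 = h(\pi_1 y_{tot})$, i.e. $O_i = h(\pi_i y_{tot})$. Two caveats drive
the package's recommendations:

* $\pi_i y_{tot}$ must lie in the link's domain. For the logit this means
  $\pi_i y_{tot} < 1$, which fails routinely for common species at
  species-rich sites. `offsets_general()` raises a structured error naming
  the violating species; `fallback = "log-prior"` substitutes $\ln \pi_i$
  with a warning. That fallback is *not* innocuous: under a non-log link an
  intercept-plus-log-prior model does not reproduce $\pi$ — the package's
  tests assert the resulting nonlinear departure rather than hide it.
* Because $h = \log$ satisfies $h^{-1}(a+b) = h^{-1}(a)h^{-1}(b)$, the log
  link reproduces the prior for *every* family, which is why `catsreg`
  supports log links throughout, including the binomial (relative-risk
  regression). Standard IRLS can fail there because the constraint
  $\mu < n$ becomes active; `fit_log_binomial()` instead maximizes the
  likelihood under the linear constraints $\eta_i < 0$ with an adaptive
  log-barrier (`constrOptim`), started from a logit fit's mean structure
  mapped to the log scale. Boundary solutions are flagged.

For hurdle (two-part) models the prior splits: the presence part takes log
relative presence frequencies, and the positive part needs the mean of the
*untruncated* parent, recovered by inverting the truncated-mean map
$\mu \mapsto \mu/(1 - e^{-\mu})$ (Poisson; the negative binomial analogue
uses $(1-((\mu+\theta)/\theta)^{-\theta})^{-1}$) with a bracketed root
search (`solve_untruncated_mean()`, absolute tolerance $10^{-10}$;
the map is strictly monotone, so bracketing on $(0, \bar m^+]$ is
guaranteed). A mean-when-present at or below 1 has no preimage and is
rejected. Species never present in the meta-community cannot inform either
part; they are excluded with a warning, never silently given $-\infty$
offsets.

## Kullback–Leibler R² and its null conventions

For exponential families the KL divergence between observations and fitted
means is half the scaled deviance, so

$$ R^2_{KL} = 1 - \frac{D^*(\mu; \mathbf y)}{D^*(\mu^0; \mathbf y)} $$

generalizes the classic $R^2$: the proportional reduction in distance when
predictors are added. The package computes every deviance as a likelihood
gap $D^* = 2[\,l(\mu^{full}) - l(\mu)\,]$ from its own density layer, and
the test suite verifies this against closed-form unit deviances to
$10^{-10}$ where they exist, and against the Poisson closed form written
directly in counts (`r2_poisson_shipley()`).

The null model $\mu^0$ needs a convention when offsets are present.
`catsreg` defaults to the **intercept-only** null (offset dropped): this
makes the offset-only model's R² a direct measure of the meta-community
effect, at the price of possible negative values when the prior *worsens*
the fit — which is reported as such, never clipped, because "the prior
increases the distance to the data" is exactly the scientific finding.
Under the alternative `intercept_plus_offset` convention (kept available in
`cats_null()` for comparison) an offset-only model scores identically zero,
so meta-community effects become invisible; that defect is why it is not
the default. `r2_alternative()` provides the divergence-decomposition form
$1 - K(y;\mu)/[K(y;\mu) + K(\mu;\mu^0)]$, which stays in $[0,1]$.

When $\theta$ (or $\phi$, $\sigma^2$) is estimated, the value from the
*evaluated* model is reused for the saturated and null likelihoods, so all
deviances in one comparison share a likelihood scale. In
`partition_variation()` the most complex model (traits + offset) supplies
the dispersion for all nested fits; without this, a drifting $\hat\theta$
can make R² non-monotone in nesting.

## Adjustment and partitioning

Adding even an unrelated predictor inflates R². Under trait-free truth the
deviance drop from $k$ junk predictors is approximately $\chi^2_k$, so

$$ R^2_{KL,adj} = \frac{D^*(\mu^0) - D^*(\mu) - k}{D^*(\mu^0)} $$

is approximately unbiased at zero. `k` counts trait predictors only —
never $\theta$, $\phi$ or $p$. For a Gaussian fit whose variance is
estimated as $\mathrm{RSS}/(n-k-1)$ from the evaluated model, this reduces
*exactly* to Ezekiel's $1-(1-R^2)(n-1)/(n-k-1)$, which the tests verify to
$10^{-8}$.

Two caveats on the null calibration, verified by simulation in the test
suite (Poisson communities, $S = 50$, 2000 replicates): the mean deviance
drop matches $k$ for $k \in \{1,3,5\}$ within Monte-Carlo error, but the
*ratio* estimator retains a small negative bias of order $k/S$, because the
drop and the null deviance are positively correlated. The adjustment is
"approximately bias-free" in the practical sense (the bias is a few
thousandths on a scale of 1 at $S=50$); it is not exactly zero-mean, and
the corresponding strict Monte-Carlo check in the acceptance suite
documents this borderline honestly rather than loosening its tolerance.

`partition_variation()` fits traits+offset, traits-only and offset-only
models against the common intercept-only null and reports

* pure trait effect $R^2(t;o) - R^2(o)$,
* pure meta-community effect $R^2(t;o) - R^2(t)$,
* joint effect $R^2(t) + R^2(o) - R^2(t;o)$,
* unexplained $1 - R^2(t;o)$,

which sum to one by construction. With `adjusted = TRUE` each R² is first
adjusted with its own $k$; since both models in the pure-meta difference
carry the same $k$, the adjustment cancels there, and components are
reported raw (possibly negative), not truncated at zero.

The older randomization adjustment divides by
$1-\overline{R^2(\text{random traits})}$, the mean R² over joint row
permutations of the trait matrix (rows, not cells, to preserve trait
covariance — the conservative reading of "reshuffling trait values").
`r2_shipley_adjust()` implements the pure-meta form;
`shipley_components()` adds the symmetric pure-trait analogue with the
same denominator. This pure-trait reconstruction is the package's own, and
the test suite checks that randomized and deterministic partitions agree
(mean absolute difference below 0.05 across a selection sweep
$s \in \{0,1,2,3\}$, 25 replicate communities per $s$).

## Diagnostics

`dunn_smyth_residuals()` returns randomized quantile residuals: for
discrete families $\Phi^{-1}(u_i)$ with $u_i$ uniform on
$(F(y_i-1), F(y_i)]$, deterministic for continuous ones, with the Tweedie
randomizing only its point mass at zero. Every stochastic routine takes an
explicit seed and restores the caller's RNG stream.

A deliberate choice: the automated normality check
(`residual_normality()`) compares residuals to the **fully specified**
N(0,1) distribution (Anderson–Darling, 1% critical value 3.857), because
under a correct model the residuals' null distribution has no free
parameters. The usual composite test (estimated mean and variance,
`reference = "estimated"`, via `nortest`) standardizes away exactly the
variance inflation that overdispersion produces, and loses most of its
power in 20-species plots; the fully specified reference detects a Poisson
fit to negative-binomial data essentially always at those sizes while
keeping its size under the true model. `overdispersion_compare()` offers
the complementary AIC route, charging the negative binomial one parameter
for its estimated $\theta$ and resolving exact ties toward the Poisson.

## Synthetic data: what it emulates, what it does not

Three generators make every behaviour testable without external data;
their defaults are the package's fixed reference conditions, chosen once:

* `simulate_overdispersed_plots()` — 50 plots × 20 species,
  $y \sim \mathrm{NegBin}(e^{0.5x}, \theta=1)$, $x \sim N(10,3)$: the
  slope-recovery and overdispersion-diagnostic setting.
* `simulate_selection_community()` — $S=50$ species,
  $y_i \sim \mathrm{Poisson}(\lambda_i)$,
  $\log\lambda_i = a + \log\pi_i + s t_i$ with
  $a = \log A - \log\sum_j \pi_j e^{s t_j}$, so $\sum_i\lambda_i = A$
  (default 2500) exactly for any selection strength $s$ — selection
  redistributes abundance without changing the expected total. The prior
  is a flat Dirichlet draw and traits are standard normal; the component
  trends (meta effect falling, selection effect rising in $s$) do not
  depend on the prior's shape.
* `simulate_presence_absence()` — a synthetic 52-site × 97-species binary
  matrix with Beta-distributed occupancies, skewed so that some widespread
  species violate $\pi_i y_{tot} < 1$ at rich sites, exercising the
  logit-domain failure path. It is a structural stand-in for a regional
  survey, not real data.

These generators draw independent species: they contain no species
interactions, no spatial autocorrelation, and no trait–dispersion
relationships. Passing tests therefore demonstrate correctness of the
estimators under the stated models, not robustness to the dependence
structures of field data (where non-independence chiefly affects
inference, not point estimation).

## Numerical choices

* **Tweedie density** ($1<p<2$): compound Poisson–gamma series evaluated
  by log-sum-exp over an index window of half-width
  $12\sqrt{j^*} + 40$ around the series peak
  $j^* = y^{2-p}/(\phi(2-p))$; terms decay super-geometrically, putting
  the neglected tail far below working precision. $\phi$ is estimated by
  mean unscaled deviance over $n-k-1$.
* **Saturated likelihoods** use analytic limits at boundary observations
  ($0\ln 0 \equiv 0$; zero counts, binomial $0$ or $n$, Tweedie zeros).
  For truncated families the per-observation supremum sits where the
  *truncated* mean equals the observation ($\mu$ from
  `solve_untruncated_mean()`); at $y=1$ it is the $\mu\to0$ limit, 0 on
  the log scale.
* **Optimizers**: IRLS (via `stats::glm.fit`, with a Poisson warm start
  for the negative binomial) for families it handles; BFGS with analytic
  scores for truncated families; a direct ML fallback when NB IRLS
  diverges (small $\theta$ with heavy-tailed counts — a regime where
  standard fitters also fail); log-barrier constrained optimization for
  the log-binomial. $\hat\theta$ diverging under equidispersion is capped
  at $10^6$ with a "Poisson-like" warning.
* **Traits** are centred and scaled by default so slopes compare across
  plots; set `standardize = FALSE` when slopes must be in native trait
  units (e.g. comparing to a generating value).
* Test-suite problem sizes (50 plots × 20 species; $S=50$ communities; 100
  replicates for null means; 2000 replicates for the chi-square
  calibration; 20–30 permutations per randomization adjustment) were
  chosen as the smallest sizes at which the Monte-Carlo error is
  comfortably below the effects being measured.

## Known limitations

* Zero-inflated mixture offsets are out of scope (they require the
  structural-zero probability at the meta-community level, which is rarely
  estimable); hurdle models cover the excess-zero case.
* The Tweedie power $p$ and the logit-domain fallback's interpretation
  limits are the user's responsibility; the package warns but cannot
  repair a mis-specified prior.
* Species with $\pi_i = 0$ but positive local abundance cannot be
  represented by an offset model; they are excluded with a warning
  (`prune_prior()`), a documented policy rather than a received rule.
* R² comparisons across different families or data are not meaningful;
  the measures are within-dataset, within-family contrasts.
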