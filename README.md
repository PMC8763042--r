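# catsreg

Generalized **C**ommunity **A**ssembly by **T**rait **S**election (CATS)
regression for community ecologists: GLMs of species abundance on traits
that carry the meta-community expectation as an offset, with
Kullback–Leibler R², deviance-based adjusted R², and partitioning of
explained variation into local-selection and meta-community components.

## The problem and the model

Local abundances reflect two forces: local selection on traits and
meta-community processes (mass effects, dispersal limitation). CATS
regression separates them without environmental data by fitting

```
h(mu_i) = beta_0 + x_i' beta + O_i
```

where `mu_i` is species *i*'s expected local abundance, `x_i` its traits,
and the offset `O_i` encodes the relative abundance `pi_i` expected *a
priori* from the meta-community. With a log link, `O_i = log(pi_i)`; for
any other link the correct offset is `h(pi_i * y_tot)`, which exists only
inside the link's domain (for the logit: `pi_i * y_tot < 1`) — one reason
the package supports log links for every family, including the constrained
log-binomial (relative-risk) model.

Supported families: Gaussian, Poisson, binomial, negative binomial (fixed
or estimated dispersion), Tweedie (`1 < p < 2`, biomass with exact zeros),
and zero-truncated Poisson/negative binomial for two-part (hurdle) models.

Explained variation is measured by the Kullback–Leibler R²,
`1 - D*(mu)/D*(mu0)` with an intercept-only null, adjusted by subtracting
the predictor count `k` from the deviance drop (its null expectation), and
partitioned via fits with traits+offset, traits only, and offset only into
pure-trait, pure-meta-community, joint, and unexplained components that sum
to one.

## Worked example

Simulate a 50-species community assembled with selection strength `s = 1`
on a Dirichlet prior (expected total abundance 2500), fit the CATS model,
and partition the variation:

```r
library(catsreg)
sim <- simulate_selection_community(s = 1, seed = 42)
f <- fit_cats(sim$abundance, sim$traits, offsets_log(sim$prior),
              "poisson", standardize = FALSE)
f
#> <cats_fit> poisson(log) + offset: S = 50, k = 1
#>             Estimate Std. Error
#> (Intercept)   7.2081     0.0301
#> trait1        1.0155     0.0167
#> logLik -137.314, scaled deviance 52.401
```

The trait slope (1.02 ± 0.02) recovers the generating selection strength
`s = 1`; the intercept absorbs the community-size scale.

```r
r2_kl(f)
#> KL R2 = 0.9910 (adjusted 0.9908; k = 1, null = intercept_only)

partition_variation(sim$abundance, sim$traits, sim$prior, "poisson")
#> <cats_partition> poisson(log), S = 50, k = 1, adjusted R2
#>          pure trait pure meta-community               joint         unexplained
#>              0.6436              0.2398              0.1074              0.0092
#> R2: both 0.9908, traits 0.7510, offset 0.3472
```

Read: traits and prior together explain 99% of the KL distance to the
data; 64% is attributable to traits alone (local selection), 24% to the
meta-community prior alone, 11% to their overlap (trait-structured
priors), and 1% remains demographic noise. Diagnostics
(`dunn_smyth_residuals()`, `overdispersion_compare()`) and hurdle-model
support (`hurdle_offsets()`, `fit_hurdle()`) are documented in the
vignette, along with the reasoning behind the intercept-only null
convention and the adjustment.

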