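---
title: "A two-class mixture of structurally different measurement models for Likert scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-class mixture of structurally different measurement models for Likert scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Likert items with an odd number of categories carry a middle category
("neither agree nor disagree") that respondents use in two qualitatively
different ways: as an ordered position between agreement and disagreement,
or as a nonresponse option chosen when they cannot or will not report an
opinion. A single polytomous IRT model cannot capture both uses, because
the second use breaks the assumption that every category choice is driven
by the trait the item measures. `mixirtree` implements a two-class person
mixture in which the two classes follow *structurally different*
measurement models that share the substantive latent traits:

* **gPCM class** (`Z_p = 1`): the person answers all `m` categories under a
  generalized partial credit model. With item slope `alpha_iR` and category
  thresholds `delta_ikR` (`delta_i1R = 0`), the probability of score `x` is
  proportional to `exp(sum_{k<=x} alpha_iR (theta - delta_ikR))`.
* **IRTree class** (`Z_p = 0`): the response passes through two nodes.
  A 2PL *skip node* first decides whether the middle category is chosen,
  `P(X* = 1) = logistic(alpha_iS (theta_0 - delta_iS))`, driven by a
  person-level skip trait `theta_0` (the tendency to give noninformative
  responses) and an item-level skip location. If the middle category is not
  chosen, the remaining `m - 1` categories are scored by a gPCM on the
  recoded outcome `X** = X - I(X > (m+1)/2)` with its own slope
  `alpha_iT` and thresholds.

Class membership `Z_p` is a person property, constant across items, with a
shared Bernoulli(`pi`) prior and a Beta(1, 1) hyper-prior on the mixing
weight. The hierarchical class prior shrinks a small class toward empty,
which is what makes a truly absent IRTree class be *estimated* as empty
instead of absorbing noise.

The two classes are linked through the person side: the substantive traits
`theta_1..theta_D` (and the skip trait) have a joint multivariate normal
distribution with zero mean, common to all persons. This "weak invariance"
linkage puts the two classes' trait estimates on one scale without
requiring any item parameters to be shared.

## Priors and identification

* Traits: `(theta_0, theta_1, ..., theta_D) ~ MVN(0, Sigma)` with an
  inverse-Wishart prior on `Sigma` (degrees of freedom `D + 3`, identity
  scale). With that df choice the posterior is dominated by the data
  whenever `N >> D + 3`.
* Slopes: log-normal with mean 0 and variance 4 on the log scale.
* Free category intercepts and the skip intercept: normal, mean 0,
  variance 10. Throughout the package, every "(a, b)" pair of a normal or
  log-normal is read as *mean and variance*.
* Identification: trait means are fixed at 0; latent variances are not
  identified, so `Sigma` is sampled freely and the state is rescaled every
  iteration: traits on dimension `d` are divided by `sqrt(Sigma_dd)`,
  slopes loading on that dimension are multiplied by it, intercepts are
  untouched, and `Sigma` becomes its correlation matrix. Because the
  linear predictors only involve products `alpha * theta` and intercepts,
  the likelihood is numerically invariant under this map (tested to
  `1e-8`), and all stored draws live on the identified unit-variance scale.

Two points here are deliberate design decisions of this package rather
than forced by the model. First, the sampler parameterizes items by
*intercepts* `beta = -alpha * delta` (their posteriors are more stable
than thresholds', and the rescaling step leaves them fixed); consequently
the diffuse normal prior is placed on the intercept scale, mirroring the
variance-10 choice made for locations. Second, category codes are 1-based
everywhere at the interface, an even number of categories is rejected
outright (the model needs a unique midpoint), and missing responses are
allowed under a missing-at-random contract: they simply drop out of every
likelihood sum.

## Estimation

The joint posterior is explored with Metropolis-Hastings-within-Gibbs.
Each sweep updates, in this fixed order:

1. `Z_p` exactly from its full conditional
   `pi L_g / (pi L_g + (1 - pi) L_h)` (log-sum-exp arithmetic);
2. each person's full trait vector by a random-walk MH step targeted at
   prior x class likelihood — for gPCM-class persons `theta_0` has no
   likelihood term and is therefore driven by its conditional prior;
3. each item's three parameter blocks `(log slope, free intercepts)` —
   gPCM-m family against gPCM-class persons, skip node and informative
   family against IRTree-class persons — proposed jointly per block
   because slope and intercepts are strongly correlated a posteriori;
4. `pi` from its conjugate Beta full conditional;
5. `Sigma` from its conjugate inverse-Wishart full conditional, followed
   by the rescaling step.

Proposal scales are adapted by Robbins-Monro toward an acceptance rate of
0.35 (midpoint of the 0.2–0.5 window) during burn-in only, and frozen
afterwards so the retained draws come from a fixed kernel. The update
order, proposal families and adaptation scheme are this package's own
sampler design; only the model equations and the conjugate structure are
fixed by the model itself.

Because one latent class can swallow the other early in a run (a chain
started with no IRTree-class persons cannot learn IRTree item parameters,
so the class empties and stays empty), several chains are run from diverse
random starts — class indicators initialized i.i.d. Bernoulli(0.5), traits
standard normal, slopes at 1, free intercepts from N(0, 0.25) — and the
chain with the highest average post-burn-in log-likelihood `L_c` is
retained. Label switching is impossible by construction: the two mixture
components have non-exchangeable structures.

Summaries use posterior means for continuous parameters, the posterior
mode for each `Z_p` (a tie at probability 0.5 is resolved to the gPCM
class, for deterministic reporting), and the share of retained iterations
spent in the gPCM class as the posterior class probability. Trait
summaries average over all retained draws and therefore mix over class
membership, propagating classification uncertainty into the trait
estimates.

The whole sweep runs in compiled code (RcppArmadillo) against R's RNG, so
a seed fixes every draw bitwise. The per-step reference implementations
(`update_class_memberships()`, `update_person_traits()`,
`update_item_parameters()`) are plain R, exported, and cross-checked
against the compiled path: a test recomputes every stored per-iteration
log-likelihood in R from the stored draws and requires agreement to
`1e-8`, and Gibbs/MH long-run behaviour is validated against grid
quadrature and closed-form conjugate posteriors on small fixtures.

## The synthetic-data generator

`sim_design()` / `simulate_mixture_data()` emulate the simulation design
the model was evaluated under:

* all `D + 1` traits i.i.d. standard normal (response tendency orthogonal
  to the substantive traits);
* the first `N * P` persons in the IRTree class, the rest gPCM —
  deterministic, kept as ground truth for evaluation only;
* `(log alpha_T, log alpha_R)` bivariate normal, means 0, variances 0.25,
  correlation .5: the two informative-response families are similar but
  not identical;
* a shared overall location `delta_bar_i ~ N(0, 1)` with fixed offsets,
  `delta_R = delta_bar + (-delta_bar, -1.5, -0.5, 0.5, 1.5)` and
  `delta_T = delta_bar + (-delta_bar, -1.5, 0, 1.5)`, so removing the
  middle category does not move the item's overall location;
* skip node `log alpha_S ~ N(-0.5, 0.25)` and `delta_S ~ N(2, 0.25)`:
  items are not designed to measure the skip tendency, and the skip
  location sits two prior standard deviations above the trait mean so
  midpoints stay a minority of IRTree-class responses.

Under these generating distributions the empirical midpoint rate within
the IRTree class comes out near 0.30 (a unit test pins it to the
0.10–0.40 band); direct integration of the skip node under the stated
distributions gives the same order, i.e. a minority share, though a
larger one than the roughly-one-in-five sometimes quoted for this design.

What the generator does *not* emulate: real response-style heterogeneity
beyond midpoint-as-nonresponse (extreme responding, acquiescence),
person-by-item class switching, missing data, or items loading on more
than one dimension. Passing the simulation benchmarks therefore shows
that the estimation machinery recovers the model's own data-generating
process at realistic sizes — not that the two-class structure is the right
description of any particular real data set.

Seeding is hierarchical: a base seed plus replication index derive
independent substreams for items, persons and responses, so item draws do
not change when the sample size does.

## Evaluation machinery

* Classification: `P_all`, `P_Tree`, `P_PCM` (restricted proportions are
  `NA` for an empty restriction) and `P_cert` (correct with posterior
  probability of the true class at least .95).
* Recovery: per scalar parameter, bias, across-replication variance in the
  *population* form (divide by the number of replications) so that
  `MSE = bias^2 + variance` holds exactly, and family averages of
  `|bias|`, variance and MSE. Identification-fixed first intercepts are
  excluded — they are constraints, not estimates.
* DIC: `D_bar` averages the deviance over retained iterations at the
  sampled parameters *including the sampled class indicators*; the plug-in
  `D_hat` evaluates the deviance at posterior means with modal class
  indicators. `p_D = D_bar - D_hat`, `DIC = 2 D_bar - D_hat`. Conditioning
  the plug-in on the modal `Z` (rather than marginalizing over it) is a
  documented choice; it matters little because well-classified persons
  have degenerate class posteriors, and for gPCM-class persons `theta_0`
  is prior-driven and contributes essentially nothing to `p_D`.
* `per_class_posthoc()` refits both nonmixture models to each assigned
  class, reproducing the design of the post-hoc DIC comparison: if each
  class really follows its own measurement model, the DIC should prefer a
  different model in each class.

## Problem sizes and numerical choices

The reference estimation settings are ten chains of 2000 iterations (1000
burn-in) — the `chain_config()` defaults. The package's shipped test suite
and acceptance script reproduce the headline results at a reduced scale
chosen as a deliberate trade-off between Monte-Carlo error and runtime:
single replications at `N = 1000, K = 40, D = 1` with four chains of 1500
iterations (750 burn-in) for the classification and trait-recovery
benchmarks, three replications at `N = 500` for the accuracy lower bound,
and five replications with two chains of 1000 iterations for the
item-recovery table. At these scales the classification proportions sit
within three printed across-replication standard deviations of the
reference values and the MSE benchmarks within +/-50%; tightening either
would require the full replication counts.

Other numerical choices: all category-probability computations subtract
the maximum cumulative predictor before exponentiation (extreme traits
stay finite); a slope of exactly zero is admitted in `gpcm_probs()` as a
degenerate input yielding the uniform distribution; likelihood ratios for
the class update are formed in log space; the inverse-Wishart draw uses
the Bartlett decomposition on the inverted posterior scale.

## Known limitations

* The IRTree component is fixed at two nodes with the midpoint as the
  skip outcome; deeper trees and other response styles are out of scope.
* Model comparison is DIC-only (no WAIC/LOO or posterior-predictive
  checks).
* Item-side scale linking between classes is not implemented; the classes
  are linked through the common trait distribution only, which is
  defensible exactly when class membership is unrelated to the traits.
* With very small classes (fewer than ~125 persons) the IRTree item
  parameters are weakly identified and the class can empty; the multiple
  chains mitigate but do not remove this.
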