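# mixirtree

Bayesian estimation of a two-class mixture item response model for Likert
scales in which the two latent classes follow **structurally different
measurement models**.

Respondents use the middle category of a Likert item ("neither agree nor
disagree") in two qualitatively different ways: as an ordered position on
the agreement scale, or as a nonresponse option. `mixirtree` models a
person mixture over these two response processes:

* **gPCM class** (`Z_p = 1`): scores on all `m` categories follow a
  generalized partial credit model,
  `P(X = x) ∝ exp(Σ_{k≤x} α_iR (θ_d − δ_ikR))`.
* **IRTree class** (`Z_p = 0`): a two-node decision tree. A 2PL skip node
  decides whether the middle category is chosen,
  `P(X* = 1) = logistic(α_iS (θ_0 − δ_iS))`, driven by a skip trait `θ_0`
  (the person's tendency to give noninformative responses); otherwise the
  remaining `m − 1` categories follow a gPCM on the recoded score
  `X** = X − I(X > (m+1)/2)`.

The classes share the substantive traits `θ_1..θ_D`, which have a common
multivariate normal distribution with the skip trait (zero means,
unit variances after per-iteration rescaling). Class membership has a
shared Bernoulli(π) prior with a Beta(1, 1) hyper-prior, so an absent
class shrinks to empty instead of absorbing noise.

Estimation is multi-chain Metropolis-Hastings-within-Gibbs (compiled core,
exactly seed-reproducible): exact conditional draws for `Z`, `π` and `Σ`,
random-walk MH for traits and item-parameter blocks, per-iteration
rescaling for identification, and best-chain selection by average
post-burn-in log-likelihood. The package also ships the simulation design
used to validate the model (correlated log-slopes, shared overall item
locations, skip node tuned so midpoints are a minority of IRTree-class
responses), classification and recovery metrics, and DIC model comparison
against nonmixture fits. See the methods vignette
(`vignettes/mixture-irtree-methods.Rmd`) for the model, priors and all
sampler design choices.

## Worked example

```r
library(mixirtree)

design <- sim_design(n_persons = 300, n_items = 20, n_dims = 1,
                     tree_fraction = 0.5, base_seed = 42)
dat <- simulate_mixture_data(design)

fit <- fit_mixture(dat$responses, dat$design,
                   config = chain_config(n_chains = 3, n_iter = 800,
                                         n_burnin = 400, seed = 1))
print(fit)
#> mixirtree fit (mixture model): 3 chains, best chain 1 (L_c = -7339.23)
#> posterior summary (mixture model), 400 retained iterations
#> gPCM class share (mean pi): 0.587; assigned to gPCM class: 187 of 300

classification_metrics(dat$persons$z, fit$summary)
#> P_all = 0.810, P_Tree = 0.687, P_PCM = 0.933, P_cert = 0.547

compute_dic(fit, dat$responses, dat$design)
#> D_bar = 14678.46, p_D = 524.86, DIC = 15203.32

theta_mse(fit, dat$persons)
#> [1] 0.167
```

The fit report shows the selected chain and its average post-burn-in
log-likelihood `L_c`; the summary gives the estimated mixing weight and
posterior-mode class assignments. With a short test (20 items) about 81%
of persons are recovered into their generating class — accuracy among
true-IRTree persons is the bottleneck, exactly the regime where a longer
test helps (40 items push overall accuracy above .90). `p_D` counts the
effective parameters entering the DIC; the skip traits of confidently
gPCM-classified persons are prior-driven and contribute almost nothing to
it. `theta_mse()` is the person-level mean squared error of the
posterior-mean primary trait against the generating values.

A thin command-line interface wraps the same functions
(`inst/cli/mixirtree simulate | fit | evaluate | compare`).

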