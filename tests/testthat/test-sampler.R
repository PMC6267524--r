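small_data <- function(N = 30, K = 6, P = 0.5, seed = 77) {
  simulate_mixture_data(sim_design(N, K, 1, P, base_seed = seed))
}

test_that("chain initialization is deterministic and well-formed", {
  dat <- small_data()
  cfg <- chain_config(n_chains = 2, n_iter = 20, n_burnin = 10, seed = 5)
  s1 <- initialize_chain(dat$responses, dat$design, cfg, 1)
  s2 <- initialize_chain(dat$responses, dat$design, cfg, 1)
  expect_identical(s1$persons$theta, s2$persons$theta)
  expect_identical(s1$persons$z, s2$persons$z)
  expect_identical(s1$items$beta_R, s2$items$beta_R)
  s3 <- initialize_chain(dat$responses, dat$design, cfg, 2)
  expect_false(identical(s1$persons$z, s3$persons$z))
  expect_true(all(s1$items$alpha_R == 1))
  expect_equal(s1$items$beta_R[, 1], rep(0, 6))
  expect_equal(s1$sigma, diag(2))
  expect_equal(s1$pi, 0.5)
})

test_that("seeded chains are bitwise reproducible and sized correctly", {
  dat <- small_data()
  prior <- prior_config(1)
  cfg <- chain_config(n_chains = 1, n_iter = 40, n_burnin = 20, seed = 9)
  d1 <- run_chain(dat$responses, dat$design, prior, cfg, 1)
  d2 <- run_chain(dat$responses, dat$design, prior, cfg, 1)
  expect_identical(d1$loglik, d2$loglik)
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$beta_R, d2$beta_R)
  expect_equal(nrow(d1$alpha_R), 20)
  # n_iter = n_burnin + 1 stores exactly one draw
  cfg1 <- chain_config(n_chains = 1, n_iter = 21, n_burnin = 20, seed = 9)
  dd <- run_chain(dat$responses, dat$design, prior, cfg1, 1)
  expect_equal(length(dd$loglik), 1L)
})

test_that("stored log-likelihoods match an independent recomputation from draws", {
  dat <- small_data(N = 12, K = 4)
  prior <- prior_config(1)
  cfg <- chain_config(n_chains = 1, n_iter = 30, n_burnin = 25, seed = 3)
  d <- run_chain(dat$responses, dat$design, prior, cfg, 1)
  for (t in seq_along(d$loglik)) {
    items_t <- item_params(alpha_R = d$alpha_R[t, ],
                           beta_R = d$beta_R[t, , ],
                           alpha_S = d$alpha_S[t, ], beta_S = d$beta_S[t, ],
                           alpha_T = d$alpha_T[t, ],
                           beta_T = d$beta_T[t, , ],
                           m = d$m)
    persons_t <- person_state(d$theta[t, , ], d$z[t, ])
    expect_equal(total_loglik(dat$responses, items_t, persons_t, dat$design),
                 d$loglik[t], tolerance = 1e-8)
  }
})

test_that("class membership full conditional matches the likelihood-ratio formula", {
  fx <- make_fixture("tiny-2x2")
  state <- list(persons = fx$persons, items = fx$items,
                sigma = diag(2), pi = 0.3)
  # direct evaluation of the ratio
  ll <- mixirtree:::class_logliks(fx$responses, fx$items, fx$persons,
                                  fx$design)
  p1 <- 0.3 * exp(ll$lg) / (0.3 * exp(ll$lg) + 0.7 * exp(ll$lh))
  set.seed(41)
  freq <- rowMeans(replicate(4000, {
    update_class_memberships(state, fx$responses, fx$design)$persons$z
  }))
  se <- sqrt(p1 * (1 - p1) / 4000)
  expect_true(all(abs(freq - p1) <= 3 * se + 1e-9))
  # pi = 1 forces the gPCM class
  state$pi <- 1 - 1e-12
  z <- update_class_memberships(state, fx$responses, fx$design)$persons$z
  expect_true(all(z == 1L))
  # equal likelihoods give P(Z = 1) = pi: identical parameter families
  it <- fx$items
  it$alpha_R <- it$alpha_T <- c(1, 1)
  it$beta_R <- rbind(c(0, 0, 0), c(0, 0, 0))
  # with equal likelihoods the conditional reduces to the prior weight;
  # check the formula directly rather than by simulation
  lleq <- list(lg = c(0, 0), lh = c(0, 0))
  expect_equal(plogis(qlogis(0.3) + lleq$lg - lleq$lh), c(0.3, 0.3))
})

test_that("trait updates target the correct posterior (quadrature oracle)", {
  # one person, two items, fixed items and Sigma: compare long-run MCMC
  # trait mean against grid quadrature of the posterior
  fx <- make_fixture("tiny-2x2")
  items <- fx$items
  design <- fx$design
  x_row <- c(2L, 1L)
  data1 <- response_matrix(matrix(x_row, 1), m = 3)
  state <- list(persons = person_state(matrix(0, 1, 2), z = 0L),
                items = items, sigma = diag(2), pi = 0.5)
  set.seed(51)
  n_it <- 3000
  draws <- matrix(NA_real_, n_it, 2)
  for (t in seq_len(n_it)) {
    state <- update_person_traits(state, data1, design, step = 0.8)
    draws[t, ] <- state$persons$theta[1, ]
  }
  keep <- draws[-(1:500), ]
  # quadrature posterior mean under the IRTree class
  grid <- seq(-5, 5, by = 0.05)
  g2 <- expand.grid(t0 = grid, t1 = grid)
  dens <- exp(-0.5 * (g2$t0^2 + g2$t1^2)) * vapply(seq_len(nrow(g2)),
    function(g) {
      exp(sum(log(c(mixture_prob(2L, 0L, g2$t0[g], g2$t1[g], items, 1),
                    mixture_prob(1L, 0L, g2$t0[g], g2$t1[g], items, 2)))))
    }, numeric(1))
  dens <- dens / sum(dens)
  post_mean <- c(sum(g2$t0 * dens), sum(g2$t1 * dens))
  mc_se <- apply(keep, 2, sd) / sqrt(nrow(keep) / 10)  # crude ESS deflation
  expect_lt(abs(mean(keep[, 1]) - post_mean[1]), 3 * mc_se[1])
  expect_lt(abs(mean(keep[, 2]) - post_mean[2]), 3 * mc_se[2])
})

test_that("traits of data-free persons follow the multivariate normal prior", {
  # all responses missing: the MH acceptance reduces to the prior ratio
  data_na <- response_matrix(matrix(c(1L, NA, NA, NA), 2, 2), m = 3)
  data_na$scores[1, 1] <- NA  # person 1 fully missing too
  items <- make_fixture("tiny-2x2")$items
  design <- test_design(c(1L, 1L))
  state <- list(persons = person_state(matrix(0, 2, 2), z = c(1L, 0L)),
                items = items, sigma = diag(2), pi = 0.5)
  set.seed(52)
  n_it <- 4000
  draws <- matrix(NA_real_, n_it, 2)
  for (t in seq_len(n_it)) {
    state <- update_person_traits(state, data_na, design, step = 1.5)
    draws[t, ] <- state$persons$theta[1, ]
  }
  keep <- draws[-(1:500), ]
  ess_factor <- 10
  se <- sqrt(ess_factor / nrow(keep))
  expect_lt(abs(mean(keep[, 1])), 3 * se)
  expect_lt(abs(sd(keep[, 1]) - 1), 3 * se)
})

test_that("item updates keep slopes positive and respect identification", {
  dat <- small_data(N = 20, K = 3)
  prior <- prior_config(1)
  state <- list(persons = dat$persons, items = dat$items, sigma = diag(2),
                pi = 0.5)
  set.seed(53)
  for (t in 1:50) {
    state <- update_item_parameters(state, dat$responses, dat$design, prior,
                                    step = 0.3)
  }
  expect_true(all(state$items$alpha_R > 0))
  expect_true(all(state$items$alpha_S > 0))
  expect_true(all(state$items$alpha_T > 0))
  expect_equal(state$items$beta_R[, 1], rep(0, 3))
  expect_equal(state$items$beta_T[, 1], rep(0, 3))
  expect_false(identical(state$items$beta_R, dat$items$beta_R))
})

test_that("MCMC class probabilities match the quadrature oracle on the tiny fixture", {
  fx <- make_fixture("tiny-2x2")
  # items, Sigma and pi fixed at the fixture values; only traits and class
  # indicators are sampled, via the reference Gibbs updates
  state <- list(persons = fx$persons, items = fx$items, sigma = diag(2),
                pi = 0.5)
  set.seed(20)
  n_it <- 6000
  zmat <- matrix(NA_integer_, n_it, 2)
  for (t in seq_len(n_it)) {
    state <- update_class_memberships(state, fx$responses, fx$design)
    state <- update_person_traits(state, fx$responses, fx$design, step = 0.8)
    zmat[t, ] <- state$persons$z
  }
  pz <- colMeans(zmat[-(1:1000), ])
  oracle <- vapply(1:2, function(p) {
    oracle_class_prob(fx$responses$scores[p, ], fx$items, fx$design,
                      diag(2), 0.5)
  }, numeric(1))
  mc_se <- sqrt(pz * (1 - pz) / (nrow(zmat) - 1000) * 10)  # ESS deflation
  expect_lt(abs(pz[1] - oracle[1]), 3 * mc_se[1] + 0.01)
  expect_lt(abs(pz[2] - oracle[2]), 3 * mc_se[2] + 0.01)
})

test_that("best-chain selection maximizes the average post-burn-in log-likelihood", {
  mk <- function(ll) list(loglik = ll)
  expect_equal(select_best_chain(list(mk(c(-500, -500)))), 1L)
  expect_equal(select_best_chain(list(mk(-500), mk(-400), mk(-450))), 2L)
  # ties break toward the lowest index
  expect_equal(select_best_chain(list(mk(-400), mk(-400))), 1L)
  expect_error(select_best_chain(list()), "no chains")
  # L_c equals the mean of the stored per-iteration log-likelihoods
  dat <- small_data(N = 10, K = 3)
  cfg <- chain_config(n_chains = 1, n_iter = 30, n_burnin = 20, seed = 2)
  d <- run_chain(dat$responses, dat$design, prior_config(1), cfg, 1)
  expect_equal(mean(d$loglik), sum(d$loglik) / length(d$loglik),
               tolerance = 1e-12)
})

test_that("posterior summaries are counting means over retained draws", {
  dat <- small_data(N = 10, K = 3)
  cfg <- chain_config(n_chains = 1, n_iter = 40, n_burnin = 30, seed = 6)
  d <- run_chain(dat$responses, dat$design, prior_config(1), cfg, 1)
  sm <- summarize_posterior(d)
  expect_equal(sm$class_prob, colMeans(d$z))
  expect_equal(sm$assignment, as.integer(colMeans(d$z) >= 0.5))
  expect_equal(sm$items$alpha_R, colMeans(d$alpha_R))
  expect_equal(sm$theta, colMeans(d$theta, dims = 1))
  expect_equal(sm$pi, mean(d$pi))
  # T = 1: the summary equals the single draw; class probability is 0/1
  cfg1 <- chain_config(n_chains = 1, n_iter = 31, n_burnin = 30, seed = 6)
  d1 <- run_chain(dat$responses, dat$design, prior_config(1), cfg1, 1)
  sm1 <- summarize_posterior(d1)
  expect_true(all(sm1$class_prob %in% c(0, 1)))
  expect_equal(sm1$items$alpha_S, as.vector(d1$alpha_S[1, ]))
})

test_that("nonmixture fits clamp class membership", {
  dat <- small_data(N = 20, K = 4)
  cfg <- chain_config(n_chains = 1, n_iter = 40, n_burnin = 20, seed = 13)
  fg <- fit_nonmixture(dat$responses, dat$design, "gpcm",
                       prior_config(1), cfg)
  expect_true(all(fg$draws$z == 1L))
  expect_true(all(fg$summary$assignment == 1L))
  ft <- fit_nonmixture(dat$responses, dat$design, "irtree",
                       prior_config(1), cfg)
  expect_true(all(ft$draws$z == 0L))
})

test_that("purely gPCM data leave the IRTree class empty", {
  sd0 <- sim_design(200, 12, 1, 0, base_seed = 303)
  dat <- simulate_mixture_data(sd0)
  cfg <- chain_config(n_chains = 3, n_iter = 500, n_burnin = 250, seed = 8)
  fit <- fit_mixture(dat$responses, dat$design, prior_config(1), cfg)
  # the hierarchical class prior shrinks an absent class to (near) empty
  expect_lt(mean(fit$summary$assignment == 0L), 0.02)
  expect_gt(fit$summary$pi, 0.9)
})
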