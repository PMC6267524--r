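#' MCMC chain configuration
#'
#' Settings of the MH-within-Gibbs sampler. Defaults follow the estimation
#' settings the model was developed with: ten chains of 2000 iterations
#' including 1000 of burn-in. Random-walk proposal scales are adapted toward
#' the target acceptance window during burn-in only (Robbins-Monro), and
#' frozen afterwards so the post-burn-in kernel satisfies detailed balance.
#'
#' @param n_chains number of independent chains. Multiple chains exist to
#'   escape the empty-class local maximum; the best chain is selected by
#'   average post-burn-in log-likelihood.
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded before summarization;
#'   must be smaller than `n_iter`.
#' @param seed integer seed; chain `c` uses a seed derived from `seed` and
#'   `c`, so runs are exactly reproducible.
#' @param proposal_sd named numeric: initial random-walk scales for the
#'   person-trait (`theta`) and item-block (`item`) proposals.
#' @param target_acceptance acceptance-rate window; adaptation drives each
#'   proposal scale toward the window midpoint.
#' @param adapt_burnin_only adapt proposal scales during burn-in only.
#' @param store_persons keep full per-iteration person draws (traits).
#'   Class indicators are always stored. Set to `FALSE` to store only
#'   running first and second moments of the traits for large problems.
#' @param sample_items,sample_sigma,sample_pi internal switches that clamp
#'   parts of the sampler at their initial values; used by oracle tests that
#'   condition on known item parameters, `Sigma` or `pi`.
#' @return Object of class `mixirt_chain_config`.
#' @export
chain_config <- function(n_chains = 10L, n_iter = 2000L, n_burnin = 1000L,
                         seed = 1L,
                         proposal_sd = c(theta = 0.5, item = 0.1),
                         target_acceptance = c(0.2, 0.5),
                         adapt_burnin_only = TRUE,
                         store_persons = TRUE,
                         sample_items = TRUE, sample_sigma = TRUE,
                         sample_pi = TRUE) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  if (n_chains < 1L) stop("`n_chains` must be >= 1")
  if (n_burnin >= n_iter) stop("`n_burnin` must be smaller than `n_iter`")
  structure(
    list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
         seed = as.integer(seed), proposal_sd = proposal_sd,
         target_acceptance = target_acceptance,
         adapt_burnin_only = isTRUE(adapt_burnin_only),
         store_persons = isTRUE(store_persons),
         sample_items = isTRUE(sample_items),
         sample_sigma = isTRUE(sample_sigma),
         sample_pi = isTRUE(sample_pi)),
    class = "mixirt_chain_config"
  )
}

chain_seed <- function(seed, chain_index) {
  as.integer((as.double(seed) + 7919 * (chain_index - 1)) %% 2147483629)
}

#' Initialize a sampler state
#'
#' Draws diverse starting values: class indicators i.i.d. Bernoulli(0.5)
#' (varying across chains, so some chains start with IRTree-class persons
#' even when the class risks emptying), standard-normal traits, unit slopes,
#' free intercepts from N(0, 0.25) (variance), identity `Sigma`, and
#' `pi = 0.5`. Deterministic given `config$seed` and `chain_index`.
#'
#' @param data a [response_matrix()] object.
#' @param design a [test_design()] vector.
#' @param config a [chain_config()] object.
#' @param chain_index chain number in `1..n_chains`.
#' @param model `"mixture"` (class indicators sampled), or `"gpcm"` /
#'   `"irtree"` (class indicators clamped to all 1 / all 0).
#' @return List of class `mixirt_state` with `persons`, `items`, `sigma`,
#'   `pi`.
#' @export
initialize_chain <- function(data, design, config, chain_index = 1L,
                             model = c("mixture", "gpcm", "irtree")) {
  model <- match.arg(model)
  set.seed(chain_seed(config$seed, chain_index))
  N <- data$n_persons; K <- data$n_items; m <- data$m
  D <- n_dims(design)
  z <- switch(model,
              mixture = stats::rbinom(N, 1L, 0.5),
              gpcm = rep(1L, N),
              irtree = rep(0L, N))
  theta <- matrix(stats::rnorm(N * (D + 1L)), N, D + 1L)
  rb <- function(nc) cbind(0, matrix(stats::rnorm(K * (nc - 1L), 0, 0.5),
                                     K, nc - 1L))
  items <- item_params(alpha_R = rep(1, K), beta_R = rb(m),
                       alpha_S = rep(1, K),
                       beta_S = stats::rnorm(K, 0, 0.5),
                       alpha_T = rep(1, K), beta_T = rb(m - 1L), m = m)
  structure(list(persons = person_state(theta, z), items = items,
                 sigma = diag(D + 1L), pi = 0.5, model = model),
            class = "mixirt_state")
}

#' Gibbs update of the class indicators (reference implementation)
#'
#' Draws each `Z_p` exactly from its full conditional,
#' `P(Z_p = 1 | .) = pi L_g / (pi L_g + (1 - pi) L_h)`, with `L_g`, `L_h`
#' the person's full response-vector likelihoods under the gPCM-m and the
#' IRTree at the current parameters. Computed in log space throughout.
#'
#' @param state a `mixirt_state` list.
#' @param data a [response_matrix()] object.
#' @param design a [test_design()] vector.
#' @return Updated state.
#' @export
update_class_memberships <- function(state, data, design) {
  ll <- class_logliks(data, state$items, state$persons, design)
  p1 <- stats::plogis(stats::qlogis(state$pi) + ll$lg - ll$lh)
  z <- as.integer(stats::runif(data$n_persons) < p1)
  state$persons <- person_state(state$persons$theta, z)
  state
}

#' Metropolis-Hastings update of the person traits (reference implementation)
#'
#' Per person, one random-walk proposal on the full `(D+1)` trait vector,
#' accepted by the product of the multivariate-normal prior `MVN(0, Sigma)`
#' and the likelihood of the person's current class. For gPCM-class persons
#' the likelihood does not involve `theta_0`, so that coordinate is driven
#' by its conditional prior given the other traits.
#'
#' @inheritParams update_class_memberships
#' @param step random-walk proposal standard deviation.
#' @return Updated state.
#' @export
update_person_traits <- function(state, data, design, step = 0.5) {
  persons <- state$persons
  N <- persons$n_persons
  D1 <- ncol(persons$theta)
  prop_theta <- persons$theta + matrix(stats::rnorm(N * D1, 0, step), N, D1)
  cur <- class_logliks(data, state$items, persons, design)
  prop <- class_logliks(data, state$items,
                        person_state(prop_theta, persons$z), design)
  omega <- solve(state$sigma)
  lprior <- function(th) -0.5 * rowSums((th %*% omega) * th)
  sel <- function(ll) ifelse(persons$z == 1L, ll$lg, ll$lh)
  log_ratio <- (sel(prop) + lprior(prop_theta)) -
    (sel(cur) + lprior(persons$theta))
  acc <- log(stats::runif(N)) < log_ratio
  theta <- persons$theta
  theta[acc, ] <- prop_theta[acc, , drop = FALSE]
  state$persons <- person_state(theta, persons$z)
  state
}

#' Metropolis-Hastings update of the item parameters (reference
#' implementation)
#'
#' Per item, three block updates on `(log slope, free intercepts)`: the
#' gPCM-m family (likelihood restricted to gPCM-class persons), the skip
#' node, and the informative gPCM-(m-1) family (both restricted to
#' IRTree-class persons). Blocks are proposed jointly because slope and
#' intercepts are strongly correlated a posteriori. Updating on the log
#' scale keeps slopes positive; identification intercepts stay zero. An
#' empty class leaves the corresponding families driven by their priors.
#'
#' @inheritParams update_class_memberships
#' @param prior a [prior_config()] object.
#' @param step random-walk proposal standard deviation per coordinate.
#' @return Updated state.
#' @export
update_item_parameters <- function(state, data, design, prior, step = 0.1) {
  items <- state$items
  persons <- state$persons
  m <- items$m
  sd_a <- sqrt(prior$log_slope_var)
  sd_b <- sqrt(prior$intercept_var)
  sd_s <- sqrt(prior$skip_intercept_var)

  item_ll <- function(it, i, cls) {
    keep <- persons$z == cls & !is.na(data$scores[, i])
    if (!any(keep)) return(0)
    ll <- 0
    for (p in which(keep)) {
      ll <- ll + log(mixture_prob(data$scores[p, i], cls,
                                  persons$theta[p, 1L],
                                  persons$theta[p, 1L + design[i]], it, i))
    }
    ll
  }
  mh <- function(i, cls, get, set, lp) {
    cur <- get(items)
    prop <- cur + stats::rnorm(length(cur), 0, step)
    items_prop <- set(items, prop)
    lr <- item_ll(items_prop, i, cls) + lp(prop) -
      item_ll(items, i, cls) - lp(cur)
    if (log(stats::runif(1L)) < lr) items <<- items_prop
  }
  for (i in seq_len(items$n_items)) {
    mh(i, 1L,
       get = function(it) c(log(it$alpha_R[i]), it$beta_R[i, -1L]),
       set = function(it, v) {
         it$alpha_R[i] <- exp(v[1L]); it$beta_R[i, -1L] <- v[-1L]; it
       },
       lp = function(v) stats::dnorm(v[1L], prior$log_slope_mean, sd_a,
                                     log = TRUE) +
         sum(stats::dnorm(v[-1L], 0, sd_b, log = TRUE)))
    mh(i, 0L,
       get = function(it) c(log(it$alpha_S[i]), it$beta_S[i]),
       set = function(it, v) {
         it$alpha_S[i] <- exp(v[1L]); it$beta_S[i] <- v[2L]; it
       },
       lp = function(v) stats::dnorm(v[1L], prior$log_slope_mean, sd_a,
                                     log = TRUE) +
         stats::dnorm(v[2L], 0, sd_s, log = TRUE))
    mh(i, 0L,
       get = function(it) c(log(it$alpha_T[i]), it$beta_T[i, -1L]),
       set = function(it, v) {
         it$alpha_T[i] <- exp(v[1L]); it$beta_T[i, -1L] <- v[-1L]; it
       },
       lp = function(v) stats::dnorm(v[1L], prior$log_slope_mean, sd_a,
                                     log = TRUE) +
         sum(stats::dnorm(v[-1L], 0, sd_b, log = TRUE)))
  }
  state$items <- items
  state
}

#' Run one MCMC chain
#'
#' Iterates the Gibbs sweep (class indicators, person traits, item
#' parameters, mixing weight, latent covariance, rescaling to the
#' identified unit-variance scale) for `n_iter` iterations, discarding
#' `n_burnin`, and records all retained draws plus the total
#' log-likelihood of each retained iteration. The heavy loop runs in
#' compiled code; identical seeds give bitwise-identical draws.
#'
#' @param data a [response_matrix()] object.
#' @param design a [test_design()] vector.
#' @param prior a [prior_config()] object.
#' @param config a [chain_config()] object.
#' @param chain_index chain number (determines the chain's seed).
#' @param model `"mixture"`, or a nonmixture fit: `"gpcm"` / `"irtree"`
#'   (class indicators clamped, mixing weight not sampled).
#' @return Object of class `mixirt_draws`: per retained iteration, item
#'   parameters, `pi`, `Sigma`, class indicators, log-likelihood, and
#'   (if `store_persons`) person traits; otherwise running trait moments.
#' @export
run_chain <- function(data, design, prior, config, chain_index = 1L,
                      model = c("mixture", "gpcm", "irtree")) {
  model <- match.arg(model)
  stopifnot(inherits(data, "mixirt_responses"),
            inherits(prior, "mixirt_prior"),
            inherits(config, "mixirt_chain_config"))
  state <- initialize_chain(data, design, config, chain_index, model)
  # initialize_chain seeds the RNG; the compiled sweep continues the stream
  X <- data$scores
  X[is.na(X)] <- -1L
  ctrl <- list(
    n_iter = config$n_iter, n_burnin = config$n_burnin,
    sample_z = (model == "mixture"),
    sample_items = config$sample_items,
    sample_sigma = config$sample_sigma,
    sample_pi = config$sample_pi && model == "mixture",
    store_persons = config$store_persons,
    adapt_burnin_only = config$adapt_burnin_only,
    target_acc = mean(config$target_acceptance),
    step_theta = unname(config$proposal_sd[["theta"]]),
    step_item = unname(config$proposal_sd[["item"]])
  )
  res <- run_chain_cpp(X, as.integer(design), data$m,
                       state$persons$theta, state$persons$z,
                       state$items$alpha_R, state$items$beta_R,
                       state$items$alpha_S, state$items$beta_S,
                       state$items$alpha_T, state$items$beta_T,
                       state$sigma, state$pi,
                       prior$sigma_df, prior$sigma_scale,
                       prior$log_slope_mean, prior$log_slope_var,
                       prior$intercept_var, prior$skip_intercept_var,
                       prior$pi_beta, ctrl)
  res$loglik <- as.numeric(res$loglik)
  res$pi <- as.numeric(res$pi)
  res$m <- data$m
  res$model <- model
  res$chain_index <- chain_index
  res$n_burnin <- config$n_burnin
  res$n_retained <- config$n_iter - config$n_burnin
  res$design <- as.integer(design)
  res$n_dims <- n_dims(design)
  class(res) <- "mixirt_draws"
  res
}

#' @export
print.mixirt_draws <- function(x, ...) {
  cat(sprintf("MCMC draws (%s model): chain %d, %d retained iterations\n",
              x$model, x$chain_index, x$n_retained))
  cat(sprintf("average post-burn-in log-likelihood: %.2f\n", mean(x$loglik)))
  invisible(x)
}

#' Select the best chain by average post-burn-in log-likelihood
#'
#' Returns the index of the chain maximizing
#' `L_c = mean_t(total log-likelihood at retained iteration t)`. Ties break
#' toward the lowest chain index. Retaining the best of several chains with
#' diverse starting values avoids solutions stuck in the empty-class local
#' maximum.
#'
#' @param all_draws list of `mixirt_draws` objects.
#' @return Integer chain index into `all_draws`.
#' @export
select_best_chain <- function(all_draws) {
  if (length(all_draws) == 0L) stop("no chains supplied")
  which.max(vapply(all_draws, function(d) mean(d$loglik), numeric(1L)))
}

#' Summarize posterior draws
#'
#' Continuous parameters are summarized by their post-burn-in means; class
#' indicators by their posterior mode, with the posterior class probability
#' estimated as the proportion of retained iterations in which the person
#' was assigned to the gPCM class. Trait summaries average over all
#' retained draws and therefore mix over class membership, so
#' classification uncertainty propagates into the trait estimates.
#'
#' @param draws a `mixirt_draws` object.
#' @return Object of class `mixirt_summary`: posterior-mean `items`,
#'   `sigma`, `pi`, `theta` (N x (D+1)), `class_prob` (P(gPCM class)) and
#'   `assignment` (1 if `class_prob >= 0.5`).
#' @export
summarize_posterior <- function(draws) {
  stopifnot(inherits(draws, "mixirt_draws"))
  T_ <- draws$n_retained
  items <- item_params(
    alpha_R = colMeans(draws$alpha_R),
    beta_R = colMeans(draws$beta_R, dims = 1L),
    alpha_S = colMeans(draws$alpha_S),
    beta_S = colMeans(draws$beta_S),
    alpha_T = colMeans(draws$alpha_T),
    beta_T = colMeans(draws$beta_T, dims = 1L),
    m = draws$m)
  theta <- if (!is.null(draws$theta)) {
    colMeans(draws$theta, dims = 1L)
  } else {
    draws$theta_sum / T_
  }
  class_prob <- colMeans(draws$z)
  structure(
    list(items = items,
         sigma = colMeans(draws$sigma, dims = 1L),
         pi = mean(draws$pi),
         theta = theta,
         class_prob = class_prob,
         assignment = as.integer(class_prob >= 0.5),
         L = mean(draws$loglik), n_retained = T_, model = draws$model),
    class = "mixirt_summary"
  )
}

#' @export
print.mixirt_summary <- function(x, ...) {
  cat(sprintf("posterior summary (%s model), %d retained iterations\n",
              x$model, x$n_retained))
  cat(sprintf("gPCM class share (mean pi): %.3f; assigned to gPCM class: %d of %d\n",
              x$pi, sum(x$assignment), length(x$assignment)))
  invisible(x)
}

fit_model <- function(data, design, model, prior, config, verbose = FALSE) {
  chains <- vector("list", config$n_chains)
  for (cc in seq_len(config$n_chains)) {
    chains[[cc]] <- run_chain(data, design, prior, config, cc, model)
    if (verbose) {
      message(sprintf("chain %d/%d: L_c = %.2f", cc, config$n_chains,
                      mean(chains[[cc]]$loglik)))
    }
  }
  L_c <- vapply(chains, function(d) mean(d$loglik), numeric(1L))
  best <- select_best_chain(chains)
  structure(
    list(model = model, chains = chains, L_c = L_c, best_chain = best,
         draws = chains[[best]],
         summary = summarize_posterior(chains[[best]]),
         config = config, prior = prior, design = as.integer(design),
         n_dims = n_dims(design)),
    class = "mixirt_fit"
  )
}

#' Fit the two-class mixture model
#'
#' Runs `n_chains` independent MH-within-Gibbs chains, selects the best by
#' average post-burn-in log-likelihood, and summarizes its posterior.
#'
#' @param data a [response_matrix()] object.
#' @param design a [test_design()] vector.
#' @param prior a [prior_config()] object (defaults match the dimensionality
#'   of `design`).
#' @param config a [chain_config()] object.
#' @param verbose print per-chain progress.
#' @return Object of class `mixirt_fit` with all chains, `L_c` per chain,
#'   the selected chain's draws and posterior summary.
#' @export
fit_mixture <- function(data, design, prior = prior_config(n_dims(design)),
                        config = chain_config(), verbose = FALSE) {
  fit_model(data, design, "mixture", prior, config, verbose)
}

#' Fit a nonmixture model with fixed class membership
#'
#' The identical sampler with the class-indicator update skipped and all
#' indicators clamped (all gPCM or all IRTree); the mixing weight is not
#' sampled. Used for model comparison against the mixture and for
#' robustness analyses of trait recovery.
#'
#' @inheritParams fit_mixture
#' @param model `"gpcm"` or `"irtree"`.
#' @return Object of class `mixirt_fit`.
#' @export
fit_nonmixture <- function(data, design, model = c("gpcm", "irtree"),
                           prior = prior_config(n_dims(design)),
                           config = chain_config(), verbose = FALSE) {
  model <- match.arg(model)
  fit_model(data, design, model, prior, config, verbose)
}

#' @export
print.mixirt_fit <- function(x, ...) {
  cat(sprintf("mixirtree fit (%s model): %d chains, best chain %d (L_c = %.2f)\n",
              x$model, length(x$chains), x$best_chain, x$L_c[x$best_chain]))
  print(x$summary)
  invisible(x)
}
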