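# Independent oracles used across the test files. These deliberately avoid
# the package's own likelihood plumbing wherever a direct evaluation is
# possible, so that implementation and oracle stay separate routes.

# gPCM category probabilities by direct evaluation of the defining ratio of
# exponentiated cumulative sums (threshold parameterization)
oracle_gpcm_thresholds <- function(theta, slope, thresholds) {
  ncat <- length(thresholds)
  num <- vapply(seq_len(ncat), function(x) {
    exp(sum(slope * (theta - thresholds[seq_len(x)])))
  }, numeric(1L))
  num / sum(num)
}

# per-person marginal likelihoods and posterior class probability on a grid:
# integrates the response-vector likelihood over the trait vector
# (theta_0, theta_d) under a bivariate normal prior with covariance sigma.
# Items, sigma and pi are held fixed.
oracle_class_prob <- function(x_row, items, design, sigma, pi,
                              grid = seq(-6, 6, by = 0.05)) {
  h <- grid[2L] - grid[1L]
  d2 <- expand.grid(t0 = grid, t1 = grid)
  w <- exp(-0.5 * rowSums((as.matrix(d2) %*% solve(sigma)) * as.matrix(d2)))
  w <- w / sum(w)
  lik <- function(z) {
    vapply(seq_len(nrow(d2)), function(g) {
      ll <- 0
      for (i in seq_along(x_row)) {
        if (is.na(x_row[i])) next
        ll <- ll + log(mixture_prob(x_row[i], z, d2$t0[g], d2$t1[g],
                                    items, i))
      }
      exp(ll)
    }, numeric(1L))
  }
  Lg <- sum(w * lik(1L))
  Lh <- sum(w * lik(0L))
  pi * Lg / (pi * Lg + (1 - pi) * Lh)
}

# small deterministic parameter set for likelihood property sweeps
random_items <- function(K, m, seed) {
  set.seed(seed)
  item_params(
    alpha_R = exp(rnorm(K, 0, 0.4)),
    beta_R = cbind(0, matrix(rnorm(K * (m - 1L), 0, 1), K)),
    alpha_S = exp(rnorm(K, -0.5, 0.4)),
    beta_S = rnorm(K, -1, 1),
    alpha_T = exp(rnorm(K, 0, 0.4)),
    beta_T = cbind(0, matrix(rnorm(K * (m - 2L), 0, 1), K)),
    m = m)
}
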