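#' Prior configuration
#'
#' Hyper-parameters of the Bayesian model, default-locked to the values the
#' model was developed with:
#' \itemize{
#'   \item latent covariance `Sigma` over `(theta_0, theta_1..theta_D)`:
#'     inverse-Wishart with `D + 3` degrees of freedom and identity scale,
#'     which makes the posterior insensitive to the prior scale once
#'     `N >> D + 3`;
#'   \item item slopes: log-normal with mean 0 and variance 4 on the log
#'     scale (relatively uninformative for the usual range of slopes);
#'   \item free category intercepts and the skip intercept: normal with mean
#'     0 and variance 10. The sampler operates on intercepts
#'     (`beta = -alpha * delta`), so the diffuse normal prior is placed on
#'     the intercept scale;
#'   \item class membership: Bernoulli(`pi`) shared across persons, with a
#'     Beta(1, 1) hyper-prior on the mixing weight `pi` (hierarchical prior;
#'     shrinks a small class toward empty).
#' }
#' All normal "(a, b)" pairs are mean/variance.
#'
#' @param n_dims number of substantive trait dimensions D.
#' @param sigma_df inverse-Wishart degrees of freedom; must exceed D.
#' @param sigma_scale (D+1) x (D+1) positive-definite scale matrix.
#' @param log_slope_mean,log_slope_var mean and variance of the normal prior
#'   on log slopes.
#' @param intercept_var variance of the normal prior on free category
#'   intercepts.
#' @param skip_intercept_var variance of the normal prior on the skip-node
#'   intercept.
#' @param pi_beta shape parameters of the Beta hyper-prior on `pi`.
#' @return Object of class `mixirt_prior`.
#' @export
prior_config <- function(n_dims = 1L,
                         sigma_df = n_dims + 3,
                         sigma_scale = diag(n_dims + 1L),
                         log_slope_mean = 0,
                         log_slope_var = 4,
                         intercept_var = 10,
                         skip_intercept_var = 10,
                         pi_beta = c(1, 1)) {
  n_dims <- as.integer(n_dims)
  if (sigma_df <= n_dims) stop("`sigma_df` must exceed the number of dimensions")
  if (any(c(log_slope_var, intercept_var, skip_intercept_var) <= 0)) {
    stop("prior variances must be positive")
  }
  if (!isTRUE(all.equal(sigma_scale, t(sigma_scale))) ||
      any(eigen(sigma_scale, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("`sigma_scale` must be symmetric positive definite")
  }
  structure(
    list(n_dims = n_dims, sigma_df = sigma_df, sigma_scale = sigma_scale,
         log_slope_mean = log_slope_mean, log_slope_var = log_slope_var,
         intercept_var = intercept_var,
         skip_intercept_var = skip_intercept_var,
         pi_beta = as.numeric(pi_beta)),
    class = "mixirt_prior"
  )
}

#' Draw the latent trait covariance from its conjugate full conditional
#'
#' The multivariate-normal traits with an inverse-Wishart hyper-prior give a
#' conjugate update: `Sigma | theta ~ IW(df0 + N, S0 + theta' theta)`. The
#' draw is obtained through `stats::rWishart` on the inverted scale.
#'
#' @param trait_matrix N x (D+1) matrix of current trait values (N may be 0,
#'   giving a draw from the prior).
#' @param prior a [prior_config()] object.
#' @return Symmetric positive-definite (D+1) x (D+1) matrix of class
#'   `matrix`.
#' @export
sample_sigma <- function(trait_matrix, prior) {
  trait_matrix <- rbind(trait_matrix)
  p <- ncol(prior$sigma_scale)
  if (nrow(trait_matrix) > 0L && ncol(trait_matrix) != p) {
    stop("`trait_matrix` must have D + 1 columns")
  }
  df <- prior$sigma_df + nrow(trait_matrix)
  S <- prior$sigma_scale + crossprod(trait_matrix)
  W <- stats::rWishart(1L, df, solve(S))[, , 1L]
  sigma <- solve(W)
  (sigma + t(sigma)) / 2
}

#' Draw the mixing weight from its conjugate full conditional
#'
#' With the Beta(a, b) hyper-prior and Bernoulli class indicators the full
#' conditional of `pi` is `Beta(a + sum(z), b + N - sum(z))`.
#'
#' @param z integer vector of class indicators (1 = gPCM class).
#' @param prior a [prior_config()] object.
#' @return A draw of `pi` in (0, 1).
#' @export
sample_pi <- function(z, prior) {
  z <- as.integer(z)
  stopifnot(all(z %in% c(0L, 1L)))
  stats::rbeta(1L, prior$pi_beta[1L] + sum(z),
               prior$pi_beta[2L] + length(z) - sum(z))
}

#' Rescale the latent scale to unit variances (identification)
#'
#' Latent variances are not identified, so `Sigma` is sampled freely and the
#' state is rescaled each iteration: for each dimension `d` with
#' `s_d = sqrt(Sigma[d, d])`, all traits on that dimension are divided by
#' `s_d` and all slopes loading on it are multiplied by `s_d` (`alpha_S` for
#' the skip dimension; `alpha_R` and `alpha_T` for the item's substantive
#' dimension). Intercepts are left untouched, so every cumulative linear
#' predictor `x * alpha * theta + B_x` -- and hence the full data
#' log-likelihood -- is numerically invariant. `Sigma` becomes its
#' correlation matrix, with unit diagonal exactly.
#'
#' @param persons a [person_state()] object.
#' @param items a [item_params()] object.
#' @param sigma current latent covariance matrix.
#' @param design a [test_design()] vector.
#' @return List with rescaled `persons`, `items` and `sigma`.
#' @export
rescale_state <- function(persons, items, sigma, design) {
  s <- sqrt(diag(sigma))
  if (any(!is.finite(s)) || any(s <= 0)) stop("`sigma` must be positive definite")
  theta <- sweep(persons$theta, 2L, s, "/")
  items2 <- items
  items2$alpha_S <- items$alpha_S * s[1L]
  sd_item <- s[1L + as.integer(design)]
  items2$alpha_R <- items$alpha_R * sd_item
  items2$alpha_T <- items$alpha_T * sd_item
  sigma2 <- sigma / tcrossprod(s)
  diag(sigma2) <- 1
  list(persons = person_state(theta, persons$z), items = items2,
       sigma = sigma2)
}

#' Log prior density of the item parameters
#'
#' Sum of log-normal log-densities for all slopes and normal log-densities
#' for all free intercepts (category intercepts beyond the first, plus the
#' skip intercept). Identification-fixed entries (`beta[, 1] == 0`)
#' contribute zero.
#'
#' @param items a [item_params()] object.
#' @param prior a [prior_config()] object.
#' @return Scalar log prior density.
#' @export
log_prior_items <- function(items, prior) {
  sd_log <- sqrt(prior$log_slope_var)
  lp <- sum(stats::dlnorm(c(items$alpha_R, items$alpha_S, items$alpha_T),
                          prior$log_slope_mean, sd_log, log = TRUE))
  sd_b <- sqrt(prior$intercept_var)
  lp <- lp + sum(stats::dnorm(items$beta_R[, -1L], 0, sd_b, log = TRUE)) +
    sum(stats::dnorm(items$beta_T[, -1L, drop = FALSE], 0, sd_b, log = TRUE))
  lp + sum(stats::dnorm(items$beta_S, 0, sqrt(prior$skip_intercept_var),
                        log = TRUE))
}
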