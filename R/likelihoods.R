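#' Generalized partial credit category probabilities
#'
#' Category probabilities of the gPCM in the slope/intercept
#' parameterization. With cumulative linear predictors
#' `s_x = sum_{k<=x} (alpha * theta + beta_k) = x * alpha * theta +
#' B_x` (where `B_x` is the cumulative intercept), the probability of
#' category `x` is `exp(s_x) / sum_s exp(s_s)`. The maximum cumulative
#' predictor is subtracted before exponentiation, so the computation is
#' stable for arbitrarily extreme `theta`.
#'
#' A slope of exactly zero is admitted as a degenerate input and yields the
#' uniform distribution over categories; negative slopes are rejected.
#'
#' @param theta latent trait value (scalar).
#' @param slope item slope, `>= 0`.
#' @param intercepts numeric vector of category intercepts, one per
#'   category, with `intercepts[1] == 0` (identification).
#' @param n_cat number of categories; defaults to `length(intercepts)`.
#' @return Probability vector of length `n_cat` summing to one.
#' @export
gpcm_probs <- function(theta, slope, intercepts, n_cat = length(intercepts)) {
  if (slope < 0) stop("`slope` must be non-negative")
  if (length(intercepts) != n_cat || n_cat < 2L) {
    stop("`intercepts` must have length n_cat >= 2")
  }
  if (intercepts[1L] != 0) stop("first intercept must be zero (identification)")
  cum <- cumsum(intercepts) + slope * theta * seq_len(n_cat)
  e <- exp(cum - max(cum))
  e / sum(e)
}

#' Probability of skipping to the middle category (IRTree first node)
#'
#' Two-parameter logistic model for the first IRTree node:
#' `P(X* = 1) = logistic(alpha_S * (theta_0 - delta_S))`, the probability
#' that a person with skip trait `theta_0` chooses the noninformative middle
#' category on an item with skip slope `alpha_S` and skip location `delta_S`.
#'
#' @param skip_trait skip trait `theta_0`.
#' @param skip_slope positive slope `alpha_S` of the skip node.
#' @param skip_location location `delta_S` of the skip node.
#' @return `P(X* = 1)` in (0, 1).
#' @export
skip_prob <- function(skip_trait, skip_slope, skip_location) {
  if (skip_slope <= 0) stop("`skip_slope` must be strictly positive")
  stats::plogis(skip_slope * (skip_trait - skip_location))
}

#' IRTree probability of a raw Likert score
#'
#' Composite probability of the two-node IRTree: the middle category has
#' probability `skip_prob(...)`; every other raw score `x` has probability
#' `(1 - skip_prob(...)) * P(X** = recode(x))` under the gPCM-(m-1) of the
#' informative node. Probabilities over all m raw categories sum to one.
#'
#' @param raw_score raw category in `1..m`.
#' @param skip_trait,theta trait values: skip trait `theta_0` and the
#'   substantive trait of the item's dimension.
#' @param skip_slope,skip_intercept 2PL skip-node parameters on the
#'   intercept scale (`skip_intercept = -skip_slope * skip_location`).
#' @param info_slope,info_intercepts gPCM-(m-1) parameters of the
#'   informative node.
#' @param m number of raw categories.
#' @return Probability of the raw score under the IRTree model.
#' @export
irtree_prob <- function(raw_score, skip_trait, theta, skip_slope,
                        skip_intercept, info_slope, info_intercepts, m) {
  if (raw_score < 1L || raw_score > m) stop("`raw_score` must lie in 1..m")
  p_skip <- stats::plogis(skip_slope * skip_trait + skip_intercept)
  mid <- (m + 1L) %/% 2L
  if (raw_score == mid) return(p_skip)
  info <- raw_score - as.integer(raw_score > mid)
  (1 - p_skip) * gpcm_probs(theta, info_slope, info_intercepts)[info]
}

#' Mixture probability of a raw Likert score
#'
#' Two-class mixture response function: persons with class indicator
#' `z = 1` respond under the gPCM-m; persons with `z = 0` respond under the
#' two-node IRTree.
#'
#' @param raw_score raw category in `1..m`.
#' @param z class indicator (1 = gPCM-m class, 0 = IRTree class).
#' @param skip_trait,theta latent traits (`theta_0` and the substantive
#'   trait of the item's dimension).
#' @param items a [item_params()] object.
#' @param item index of the item within `items`.
#' @return Probability of the raw score.
#' @export
mixture_prob <- function(raw_score, z, skip_trait, theta, items, item) {
  stopifnot(inherits(items, "mixirt_items"), z %in% c(0L, 1L))
  if (z == 1L) {
    gpcm_probs(theta, items$alpha_R[item], items$beta_R[item, ])[raw_score]
  } else {
    irtree_prob(raw_score, skip_trait, theta,
                items$alpha_S[item], items$beta_S[item],
                items$alpha_T[item], items$beta_T[item, ], items$m)
  }
}

#' Log-likelihood of one person's response vector
#'
#' Sum over the person's non-missing responses of the log mixture
#' probability at the person's current traits and class. Missing responses
#' contribute zero (missing-at-random contract).
#'
#' @param responses integer vector of raw scores (length K, `NA` allowed).
#' @param skip_trait,theta_vec person traits: `theta_0` and the vector
#'   `theta_1..theta_D`.
#' @param z class indicator.
#' @param items a [item_params()] object.
#' @param design a [test_design()] vector mapping items to dimensions.
#' @return Scalar log-likelihood.
#' @export
person_loglik <- function(responses, skip_trait, theta_vec, z, items, design) {
  ll <- 0
  for (i in seq_along(responses)) {
    x <- responses[i]
    if (is.na(x)) next
    ll <- ll + log(mixture_prob(x, z, skip_trait, theta_vec[design[i]],
                                items, i))
  }
  ll
}

#' Total log-likelihood and deviance of a response matrix
#'
#' `total_loglik()` sums [person_loglik()] over persons at the given state;
#' `total_deviance()` is `-2` times that sum. The deviance conditions on the
#' class indicators in `persons`, so it is the quantity averaged over
#' iterations for the DIC.
#'
#' @param data a [response_matrix()] object.
#' @param items a [item_params()] object.
#' @param persons a [person_state()] object.
#' @param design a [test_design()] vector.
#' @return Scalar log-likelihood / deviance.
#' @export
total_loglik <- function(data, items, persons, design) {
  stopifnot(inherits(data, "mixirt_responses"),
            inherits(persons, "mixirt_persons"))
  ll <- 0
  for (p in seq_len(data$n_persons)) {
    ll <- ll + person_loglik(data$scores[p, ], persons$theta[p, 1L],
                             persons$theta[p, -1L, drop = FALSE][1L, ],
                             persons$z[p], items, design)
  }
  ll
}

#' @rdname total_loglik
#' @export
total_deviance <- function(data, items, persons, design) {
  -2 * total_loglik(data, items, persons, design)
}

# Per-person log-likelihoods under both classes, vectorized over persons.
# Returns list(lg, lh): N-vectors of full response-vector log-likelihoods
# under the gPCM-m class and the IRTree class. Used by the R reference
# updates and by test oracles; the compiled sampler has its own kernel.
class_logliks <- function(data, items, persons, design) {
  N <- data$n_persons
  m <- data$m
  mid <- (m + 1L) %/% 2L
  lg <- numeric(N)
  lh <- numeric(N)
  th0 <- persons$theta[, 1L]
  for (i in seq_len(data$n_items)) {
    x <- data$scores[, i]
    obs <- !is.na(x)
    if (!any(obs)) next
    thd <- persons$theta[, 1L + design[i]]
    # gPCM-m: N x m cumulative predictors
    cumR <- cumsum(items$beta_R[i, ])
    sR <- outer(items$alpha_R[i] * thd, seq_len(m)) +
      matrix(cumR, N, m, byrow = TRUE)
    sR <- sR - apply(sR, 1L, max)
    lpR <- sR - log(rowSums(exp(sR)))
    lg[obs] <- lg[obs] + lpR[cbind(which(obs), x[obs])]
    # IRTree
    u <- items$alpha_S[i] * th0 + items$beta_S[i]
    lp_skip <- stats::plogis(u, log.p = TRUE)
    lp_noskip <- stats::plogis(-u, log.p = TRUE)
    cumT <- cumsum(items$beta_T[i, ])
    sT <- outer(items$alpha_T[i] * thd, seq_len(m - 1L)) +
      matrix(cumT, N, m - 1L, byrow = TRUE)
    sT <- sT - apply(sT, 1L, max)
    lpT <- sT - log(rowSums(exp(sT)))
    is_mid <- obs & x == mid
    not_mid <- obs & x != mid
    lh[is_mid] <- lh[is_mid] + lp_skip[is_mid]
    if (any(not_mid)) {
      info <- x[not_mid] - as.integer(x[not_mid] > mid)
      lh[not_mid] <- lh[not_mid] + lp_noskip[not_mid] +
        lpT[cbind(which(not_mid), info)]
    }
  }
  list(lg = lg, lh = lh)
}
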