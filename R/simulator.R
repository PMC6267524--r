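#' Simulation design for the mixture model
#'
#' Describes one cell of the data-generating design: sample size, test
#' length, number of substantive dimensions (items split equally across
#' dimensions), the true proportion of persons in the IRTree class, and the
#' number of categories (five-point Likert scales).
#'
#' @param n_persons number of persons N.
#' @param n_items number of items K; must be divisible by `n_dims`.
#' @param n_dims number of substantive dimensions D.
#' @param tree_fraction true proportion P of persons in the IRTree class;
#'   `N * P` must be an integer.
#' @param m number of categories (odd; the generating threshold sets are
#'   defined for `m = 5`).
#' @param n_replications number of replicated data sets.
#' @param base_seed master seed; each replication and random source
#'   (items / persons / responses) gets its own derived substream, so item
#'   draws do not depend on `n_persons`.
#' @return Object of class `mixirt_simdesign`.
#' @export
sim_design <- function(n_persons, n_items, n_dims = 1L, tree_fraction = 0.5,
                       m = 5L, n_replications = 1L, base_seed = 1L) {
  n_persons <- as.integer(n_persons); n_items <- as.integer(n_items)
  n_dims <- as.integer(n_dims); m <- as.integer(m)
  if (m %% 2L == 0L || m < 3L) stop("`m` must be odd and >= 3")
  if (n_items %% n_dims != 0L) stop("`n_items` must be divisible by `n_dims`")
  n_tree <- n_persons * tree_fraction
  if (abs(n_tree - round(n_tree)) > 1e-9) {
    stop("`n_persons * tree_fraction` must be an integer")
  }
  structure(
    list(n_persons = n_persons, n_items = n_items, n_dims = n_dims,
         tree_fraction = tree_fraction, m = m,
         n_replications = as.integer(n_replications),
         base_seed = as.integer(base_seed),
         dims = test_design(rep(seq_len(n_dims), each = n_items %/% n_dims))),
    class = "mixirt_simdesign"
  )
}

# Deterministic substream seed: base seed, replication index, and a stream
# label mapped into [0, 2^31). Keeps item draws identical across sample
# sizes and replications independent.
sim_seed <- function(base_seed, replication, stream) {
  streams <- c(items = 1L, persons = 2L, responses = 3L)
  s <- (as.double(base_seed) * 2654435761 + replication * 97561 +
          streams[[stream]] * 7919) %% 2147483629
  as.integer(s)
}

#' Draw generating item parameters
#'
#' Generates the item side of a simulated data set:
#' \itemize{
#'   \item `(log alpha_T, log alpha_R)` from a bivariate normal with means
#'     0, variances 0.25 and correlation .5 -- the two informative-response
#'     families are similar but not identical;
#'   \item an overall item location `delta_bar_i ~ N(0, 1)` shared by both
#'     families: `delta_R = delta_bar + (-delta_bar, -1.5, -0.5, 0.5, 1.5)`
#'     and `delta_T = delta_bar + (-delta_bar, -1.5, 0, 1.5)`, so dropping
#'     the middle category does not move the item's overall location and
#'     the first threshold of each family is exactly 0;
#'   \item skip node: `log alpha_S ~ N(-0.5, 0.25)` (items were not designed
#'     to measure the skip tendency, hence low slopes) and
#'     `delta_S ~ N(2, 0.25)`, placing the skip node well above the trait
#'     mean so only a minority of IRTree-class responses are midpoints.
#' }
#' All "(a, b)" pairs are mean/variance. Thresholds are converted to the
#' canonical intercepts `beta = -alpha * delta`.
#'
#' @param design a [sim_design()] object (requires `m = 5`; the printed
#'   threshold offset sets are specific to five categories).
#' @param replication replication index used for seeding.
#' @return A [item_params()] object; the generating thresholds are attached
#'   as attribute `"thresholds"` (list `delta_R`, `delta_S`, `delta_T`,
#'   `delta_bar`).
#' @export
draw_generating_parameters <- function(design, replication = 1L) {
  stopifnot(inherits(design, "mixirt_simdesign"))
  if (design$m != 5L) {
    stop("the generating threshold sets are defined for m = 5")
  }
  set.seed(sim_seed(design$base_seed, replication, "items"))
  K <- design$n_items
  # bivariate normal on (log alpha_T, log alpha_R): var .25, cor .5
  z1 <- stats::rnorm(K); z2 <- stats::rnorm(K)
  log_aT <- 0.5 * z1
  log_aR <- 0.5 * (0.5 * z1 + sqrt(1 - 0.25) * z2)
  alpha_T <- exp(log_aT); alpha_R <- exp(log_aR)
  delta_bar <- stats::rnorm(K, 0, 1)
  delta_R <- cbind(0, delta_bar - 1.5, delta_bar - 0.5,
                   delta_bar + 0.5, delta_bar + 1.5)
  delta_T <- cbind(0, delta_bar - 1.5, delta_bar, delta_bar + 1.5)
  alpha_S <- exp(stats::rnorm(K, -0.5, 0.5))
  delta_S <- stats::rnorm(K, 2, 0.5)
  items <- item_params(
    alpha_R = alpha_R,
    beta_R = thresholds_to_intercepts(alpha_R, delta_R),
    alpha_S = alpha_S,
    beta_S = thresholds_to_intercepts(alpha_S, delta_S),
    alpha_T = alpha_T,
    beta_T = thresholds_to_intercepts(alpha_T, delta_T),
    m = design$m
  )
  attr(items, "thresholds") <- list(delta_R = delta_R, delta_S = delta_S,
                                    delta_T = delta_T, delta_bar = delta_bar)
  items
}

#' Draw generating person parameters
#'
#' All `D + 1` traits (the skip trait and the substantive traits) are drawn
#' i.i.d. standard normal -- the response tendency is orthogonal to the
#' traits of interest. Class membership is assigned deterministically: the
#' first `N * P` persons belong to the IRTree class (`z = 0`), the rest to
#' the gPCM class (`z = 1`). The labels are ground truth for evaluation and
#' are never passed to the sampler.
#'
#' @param design a [sim_design()] object.
#' @param replication replication index used for seeding.
#' @return A [person_state()] object.
#' @export
draw_persons <- function(design, replication = 1L) {
  stopifnot(inherits(design, "mixirt_simdesign"))
  set.seed(sim_seed(design$base_seed, replication, "persons"))
  N <- design$n_persons
  theta <- matrix(stats::rnorm(N * (design$n_dims + 1L)), N,
                  design$n_dims + 1L)
  n_tree <- as.integer(round(N * design$tree_fraction))
  z <- c(rep(0L, n_tree), rep(1L, N - n_tree))
  person_state(theta, z)
}

#' Simulate a response matrix from the mixture model
#'
#' Draws each `X[p, i]` from the categorical distribution implied by the
#' mixture response function at the person's true class and traits. No
#' cells are missing.
#'
#' @param items a [item_params()] object (generating values).
#' @param persons a [person_state()] object (generating values).
#' @param design a [sim_design()] object.
#' @param replication replication index used for seeding.
#' @return A [response_matrix()] object.
#' @export
simulate_responses <- function(items, persons, design, replication = 1L) {
  stopifnot(inherits(design, "mixirt_simdesign"))
  set.seed(sim_seed(design$base_seed, replication, "responses"))
  N <- persons$n_persons
  K <- items$n_items
  m <- items$m
  mid <- (m + 1L) %/% 2L
  dims <- design$dims
  X <- matrix(NA_integer_, N, K)
  is_g <- persons$z == 1L
  th0 <- persons$theta[, 1L]
  for (i in seq_len(K)) {
    thd <- persons$theta[, 1L + dims[i]]
    P <- matrix(0, N, m)
    # gPCM-m class
    cumR <- cumsum(items$beta_R[i, ])
    sR <- outer(items$alpha_R[i] * thd, seq_len(m)) +
      matrix(cumR, N, m, byrow = TRUE)
    sR <- exp(sR - apply(sR, 1L, max))
    P[is_g, ] <- sR[is_g, , drop = FALSE] / rowSums(sR)[is_g]
    # IRTree class
    if (any(!is_g)) {
      p_skip <- stats::plogis(items$alpha_S[i] * th0 + items$beta_S[i])
      cumT <- cumsum(items$beta_T[i, ])
      sT <- outer(items$alpha_T[i] * thd, seq_len(m - 1L)) +
        matrix(cumT, N, m - 1L, byrow = TRUE)
      sT <- exp(sT - apply(sT, 1L, max))
      pT <- sT / rowSums(sT)
      Ph <- cbind(pT[, seq_len(mid - 1L), drop = FALSE], p_skip,
                  pT[, mid:(m - 1L), drop = FALSE]) *
        cbind(matrix(1 - p_skip, N, mid - 1L), 1,
              matrix(1 - p_skip, N, m - mid))
      P[!is_g, ] <- Ph[!is_g, , drop = FALSE]
    }
    u <- stats::runif(N)
    X[, i] <- 1L + as.integer(rowSums(t(apply(P, 1L, cumsum)) < u))
  }
  response_matrix(X, m)
}

#' Simulate one complete data set (items, persons, responses)
#'
#' @param design a [sim_design()] object.
#' @param replication replication index.
#' @return List with `responses`, `items`, `persons`, `design` (the
#'   item-to-dimension vector) and `simdesign`.
#' @export
simulate_mixture_data <- function(design, replication = 1L) {
  items <- draw_generating_parameters(design, replication)
  persons <- draw_persons(design, replication)
  responses <- simulate_responses(items, persons, design, replication)
  list(responses = responses, items = items, persons = persons,
       design = design$dims, simdesign = design)
}

#' Proportion of midpoint responses among IRTree-class persons
#'
#' @param data a [response_matrix()] object.
#' @param persons a [person_state()] object with true classes.
#' @return Proportion of observed responses of true-IRTree persons equal to
#'   the middle category.
#' @export
midpoint_rate <- function(data, persons) {
  mid <- (data$m + 1L) %/% 2L
  x <- data$scores[persons$z == 0L, , drop = FALSE]
  mean(x == mid, na.rm = TRUE)
}

#' Small deterministic fixtures for tests and examples
#'
#' Fully specified miniature instances:
#' \describe{
#'   \item{"tiny-2x2"}{2 persons, 2 items, `m = 3`, hand-picked parameters;
#'     the instance used by the quadrature oracle checks.}
#'   \item{"oracle-3cat"}{1 person, 3 items, `m = 3`, unit slopes and simple
#'     intercepts for hand-computable likelihoods.}
#'   \item{"gpcm-only"}{60 persons, 8 items, `m = 5`, `P = 0` (all persons
#'     in the gPCM class), for empty-class behaviour tests.}
#' }
#'
#' @param name fixture label.
#' @return List with `responses`, `items`, `persons`, `design`.
#' @export
make_fixture <- function(name = c("tiny-2x2", "oracle-3cat", "gpcm-only")) {
  name <- match.arg(name)
  if (name == "tiny-2x2") {
    items <- item_params(
      alpha_R = c(1.2, 0.8), beta_R = rbind(c(0, 0.5, -0.5), c(0, -0.3, 0.4)),
      alpha_S = c(0.7, 1.0), beta_S = c(-0.8, -1.2),
      alpha_T = c(1.0, 1.1), beta_T = rbind(c(0, -0.4), c(0, 0.6)),
      m = 3L)
    persons <- person_state(rbind(c(0.5, -1.0), c(-0.2, 1.3)), z = c(0L, 1L))
    responses <- response_matrix(rbind(c(2L, 1L), c(3L, 2L)), m = 3L)
    design <- test_design(c(1L, 1L))
  } else if (name == "oracle-3cat") {
    items <- item_params(
      alpha_R = rep(1, 3), beta_R = rbind(c(0, 1, -1), c(0, 0, 0), c(0, -0.5, 0.5)),
      alpha_S = rep(1, 3), beta_S = c(0, -1, 1),
      alpha_T = rep(1, 3), beta_T = rbind(c(0, 0), c(0, 0.5), c(0, -0.5)),
      m = 3L)
    persons <- person_state(rbind(c(0, 0)), z = 1L)
    responses <- response_matrix(rbind(c(1L, 2L, 3L)), m = 3L)
    design <- test_design(rep(1L, 3))
  } else {
    sd <- sim_design(n_persons = 60L, n_items = 8L, n_dims = 1L,
                     tree_fraction = 0, m = 5L, base_seed = 424242L)
    dat <- simulate_mixture_data(sd)
    return(list(responses = dat$responses, items = dat$items,
                persons = dat$persons, design = dat$design))
  }
  list(responses = responses, items = items, persons = persons,
       design = design)
}
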