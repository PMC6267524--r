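test_that("recoding maps raw scores to skip indicator and informative score", {
  # m = 5: enumerate all categories
  raw <- response_matrix(matrix(1:5, nrow = 1), m = 5)
  rec <- recode_responses(raw)
  expect_equal(as.vector(rec$skip), c(0L, 0L, 1L, 0L, 0L))
  expect_equal(as.vector(rec$info), c(1L, 2L, NA, 3L, 4L))

  # m = 7: oracle = direct enumeration of X - I(X > (m+1)/2)
  raw7 <- response_matrix(matrix(1:7, nrow = 1), m = 7)
  rec7 <- recode_responses(raw7)
  oracle_info <- ifelse(1:7 == 4L, NA_integer_,
                        1:7 - as.integer(1:7 > 4L))
  expect_equal(as.vector(rec7$skip), as.integer(1:7 == 4L))
  expect_equal(as.vector(rec7$info), oracle_info)

  # missing raw scores propagate
  rawna <- response_matrix(matrix(c(2L, NA), nrow = 1), m = 5)
  recna <- recode_responses(rawna)
  expect_true(is.na(recna$skip[1, 2]) && is.na(recna$info[1, 2]))
})

test_that("raw scores are exactly recoverable from the recoded outcomes", {
  for (m in c(3L, 5L, 7L)) {
    mid <- (m + 1L) %/% 2L
    raw <- response_matrix(matrix(seq_len(m), nrow = 1), m = m)
    rec <- recode_responses(raw)
    back <- ifelse(rec$skip == 1L, mid,
                   rec$info + as.integer(rec$info >= mid))
    expect_equal(as.vector(back), seq_len(m))
  }
})

test_that("invalid response matrices are rejected", {
  expect_error(response_matrix(matrix(1:4, 2), m = 4), "odd")
  expect_error(response_matrix(matrix(c(1L, 6L), 1), m = 5), "out of range")
  expect_error(response_matrix(matrix(integer(0), 0, 0)), "at least one")
})

test_that("gPCM probabilities match hand and threshold-oracle evaluations", {
  # thresholds (0, -1, 1): unnormalized scores (1, e, 1) at theta = 0
  p <- gpcm_probs(0, 1, thresholds_to_intercepts(1, c(0, -1, 1)))
  expect_equal(p, c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_equal(p, c(0.2119, 0.5761, 0.2119), tolerance = 5e-4)

  # random configurations against the threshold-form oracle
  set.seed(42)
  for (r in 1:20) {
    ncat <- sample(2:7, 1)
    th <- rnorm(1, 0, 2)
    a <- exp(rnorm(1, 0, 0.5))
    d <- c(0, rnorm(ncat - 1))
    expect_equal(gpcm_probs(th, a, thresholds_to_intercepts(a, d)),
                 oracle_gpcm_thresholds(th, a, d), tolerance = 1e-12)
  }
})

test_that("gPCM degenerate and limiting cases", {
  # zero slope: uniform over categories
  expect_equal(gpcm_probs(1.3, 0, rep(0, 4)), rep(0.25, 4))
  # two categories at the item location: a 2PL at its point of indifference
  a <- 1.7; d2 <- 0.8
  expect_equal(gpcm_probs(d2, a, c(0, -a * d2)), c(0.5, 0.5),
               tolerance = 1e-12)
  # 2 categories coincide with the 2PL at arbitrary (theta, a, d)
  set.seed(1)
  for (r in 1:10) {
    th <- rnorm(1); a <- exp(rnorm(1, 0, 0.5)); d <- rnorm(1)
    p2 <- gpcm_probs(th, a, c(0, -a * d))
    expect_equal(p2[2], plogis(a * (th - d)), tolerance = 1e-12)
  }
  # extreme trait stays finite and normalized
  p <- gpcm_probs(200, 2, c(0, 1, -1, 0.5, 2))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(gpcm_probs(0, -1, c(0, 1)), "non-negative")
  expect_error(gpcm_probs(0, 1, c(0.5, 1)), "first intercept")
})

test_that("skip probability is the 2PL at the skip node", {
  expect_equal(skip_prob(2, 0.7, 2), 0.5)
  expect_equal(skip_prob(0, 0.7, 2), 1 / (1 + exp(1.4)), tolerance = 1e-12)
  expect_equal(round(skip_prob(0, 0.7, 2), 5), 0.19782)
  expect_equal(skip_prob(-50, 1, 0), 0, tolerance = 1e-12)
  expect_error(skip_prob(0, 0, 1), "positive")
})

test_that("IRTree probabilities combine the two nodes and normalize", {
  m <- 5L
  aS <- 0.9; bS <- -1.1; aT <- 1.2
  bT <- c(0, -0.5, 0.2, 0.8)
  th0 <- 0.4; th <- -0.7
  p_skip <- plogis(aS * th0 + bS)
  # middle category: exactly the skip probability
  expect_equal(irtree_prob(3L, th0, th, aS, bS, aT, bT, m), p_skip)
  # non-middle: (1 - skip) times the informative gPCM-(m-1) category
  p4 <- gpcm_probs(th, aT, bT)
  expect_equal(irtree_prob(5L, th0, th, aS, bS, aT, bT, m),
               (1 - p_skip) * p4[4], tolerance = 1e-12)
  # law of total probability over all raw categories
  tot <- sum(vapply(1:5, irtree_prob, numeric(1), skip_trait = th0,
                    theta = th, skip_slope = aS, skip_intercept = bS,
                    info_slope = aT, info_intercepts = bT, m = m))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("mixture probability selects the class branch and normalizes", {
  items <- random_items(3, 5, seed = 9)
  th0 <- 0.3; th <- -1.2
  for (i in 1:3) {
    for (x in 1:5) {
      expect_identical(mixture_prob(x, 1L, th0, th, items, i),
                       gpcm_probs(th, items$alpha_R[i], items$beta_R[i, ])[x])
      expect_identical(mixture_prob(x, 0L, th0, th, items, i),
                       irtree_prob(x, th0, th, items$alpha_S[i],
                                   items$beta_S[i], items$alpha_T[i],
                                   items$beta_T[i, ], 5L))
    }
    for (z in 0:1) {
      tot <- sum(vapply(1:5, mixture_prob, numeric(1), z = z,
                        skip_trait = th0, theta = th, items = items,
                        item = i))
      expect_equal(tot, 1, tolerance = 1e-12)
    }
  }
})

test_that("threshold and intercept parameterizations give identical probabilities", {
  set.seed(11)
  for (r in 1:10) {
    ncat <- sample(3:6, 1)
    a <- exp(rnorm(1, 0, 0.5))
    d <- c(0, rnorm(ncat - 1))
    b <- thresholds_to_intercepts(a, d)
    expect_equal(intercepts_to_thresholds(a, b), d, tolerance = 1e-12)
    th <- rnorm(1, 0, 2)
    expect_equal(gpcm_probs(th, a, b), oracle_gpcm_thresholds(th, a, d),
                 tolerance = 1e-12)
  }
})

test_that("person log-likelihood is additive and skips missing responses", {
  fx <- make_fixture("tiny-2x2")
  items <- fx$items
  # empty response vector contributes zero
  expect_equal(person_loglik(c(NA_integer_, NA_integer_), 0.5, -1, 1L,
                             items, fx$design), 0)
  # matches brute-force product of per-item mixture probabilities
  for (p in 1:2) {
    direct <- prod(vapply(1:2, function(i) {
      mixture_prob(fx$responses$scores[p, i], fx$persons$z[p],
                   fx$persons$theta[p, 1], fx$persons$theta[p, 2], items, i)
    }, numeric(1)))
    expect_equal(person_loglik(fx$responses$scores[p, ],
                               fx$persons$theta[p, 1],
                               fx$persons$theta[p, 2],
                               fx$persons$z[p], items, fx$design),
                 log(direct), tolerance = 1e-12)
  }
})

test_that("total deviance is -2 times the summed person log-likelihoods", {
  fx <- make_fixture("tiny-2x2")
  ll <- sum(vapply(1:2, function(p) {
    person_loglik(fx$responses$scores[p, ], fx$persons$theta[p, 1],
                  fx$persons$theta[p, 2], fx$persons$z[p], fx$items,
                  fx$design)
  }, numeric(1)))
  expect_equal(total_loglik(fx$responses, fx$items, fx$persons, fx$design),
               ll, tolerance = 1e-12)
  expect_equal(total_deviance(fx$responses, fx$items, fx$persons, fx$design),
               -2 * ll, tolerance = 1e-12)
})

test_that("vectorized class log-likelihoods agree with the scalar route", {
  set.seed(23)
  m <- 5L; K <- 6L; N <- 7L
  items <- random_items(K, m, seed = 5)
  X <- matrix(sample(1:m, N * K, replace = TRUE), N, K)
  X[1, 2] <- NA
  data <- response_matrix(X, m)
  design <- test_design(rep(1L, K))
  persons <- person_state(matrix(rnorm(N * 2), N, 2),
                          z = rep(c(0L, 1L), length.out = N))
  ll <- mixirtree:::class_logliks(data, items, persons, design)
  for (p in seq_len(N)) {
    for (z in 0:1) {
      direct <- person_loglik(X[p, ], persons$theta[p, 1],
                              persons$theta[p, 2], z, items, design)
      expect_equal(if (z == 1) ll$lg[p] else ll$lh[p], direct,
                   tolerance = 1e-10)
    }
  }
})
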