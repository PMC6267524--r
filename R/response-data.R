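#' Construct a response matrix of polytomous Likert scores
#'
#' Wraps an `N x K` matrix of integer item scores in `{1, ..., m}` together
#' with the number of response categories `m`. The model requires an odd `m`
#' so that the scale has a unique middle category `(m + 1) / 2`, which the
#' IRTree measurement model treats as a nonresponse option. Missing responses
#' are allowed (`NA`) and are skipped in all likelihood computations.
#'
#' @param scores matrix or data frame of integer scores; rows are persons,
#'   columns are items. `NA` marks a missing response.
#' @param m number of response categories. Must be odd and at least 3. If
#'   `NULL`, the smallest odd integer not below the maximum observed score is
#'   used (and must equal that maximum).
#' @return An object of class `mixirt_responses` with elements `scores`
#'   (integer matrix), `m`, `n_persons` and `n_items`.
#' @export
response_matrix <- function(scores, m = NULL) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) stop("`scores` must be a matrix or data frame")
  storage.mode(scores) <- "integer"
  if (nrow(scores) < 1L || ncol(scores) < 1L) {
    stop("response matrix must have at least one person and one item")
  }
  obs <- scores[!is.na(scores)]
  if (length(obs) == 0L && is.null(m)) {
    stop("cannot infer `m` from an all-missing matrix")
  }
  if (is.null(m)) m <- max(obs)
  m <- as.integer(m)
  if (m < 3L || m %% 2L == 0L) {
    stop("`m` must be an odd integer >= 3 (the model needs a unique middle category); got ", m)
  }
  bad <- which(!is.na(scores) & (scores < 1L | scores > m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("score out of range [1, %d] at row %d, column %d",
                 m, bad[1L, 1L], bad[1L, 2L]))
  }
  structure(
    list(scores = scores, m = m,
         n_persons = nrow(scores), n_items = ncol(scores)),
    class = "mixirt_responses"
  )
}

#' @export
print.mixirt_responses <- function(x, ...) {
  cat(sprintf("Likert response matrix: %d persons x %d items, m = %d categories\n",
              x$n_persons, x$n_items, x$m))
  cat(sprintf("missing cells: %d\n", sum(is.na(x$scores))))
  invisible(x)
}

#' Construct an item-to-dimension design vector
#'
#' @param dims integer vector of length K giving, for each item, the
#'   dimension (in `1..D`) of the primary trait it measures.
#' @param n_dims number of dimensions D; defaults to `max(dims)`. Every
#'   dimension label in `1..D` must occur for at least one item.
#' @return Integer vector of class `mixirt_design` with attribute `n_dims`.
#' @export
test_design <- function(dims, n_dims = max(dims)) {
  dims <- as.integer(dims)
  n_dims <- as.integer(n_dims)
  if (any(is.na(dims)) || any(dims < 1L) || any(dims > n_dims)) {
    stop("dimension labels must lie in 1..", n_dims)
  }
  if (!all(seq_len(n_dims) %in% dims)) {
    stop("every dimension in 1..", n_dims, " must be assigned at least one item")
  }
  structure(dims, n_dims = n_dims, class = "mixirt_design")
}

n_dims <- function(design) attr(design, "n_dims")

#' Recode raw Likert scores into IRTree node outcomes
#'
#' The IRTree measurement model decomposes each raw score `X` into a binary
#' skip indicator `X* = I(X == (m+1)/2)` (the first node: was the middle,
#' noninformative category chosen?) and, when the middle category was not
#' chosen, an informative score on `m - 1` categories,
#' `X** = X - I(X > (m+1)/2)` (the second node). When `X* = 1` the response
#' process terminated at the first node and `X**` is undefined (`NA`).
#' Missing raw scores propagate to `NA` in both outputs.
#'
#' @param raw a [response_matrix()] object.
#' @return A list of class `mixirt_recoded` with integer matrices `skip`
#'   (0/1) and `info` (values in `1..m-1`, `NA` where undefined), plus `m`.
#' @export
recode_responses <- function(raw) {
  stopifnot(inherits(raw, "mixirt_responses"))
  x <- raw$scores
  mid <- (raw$m + 1L) %/% 2L
  skip <- ifelse(is.na(x), NA_integer_, as.integer(x == mid))
  info <- ifelse(is.na(x) | x == mid, NA_integer_, x - as.integer(x > mid))
  structure(list(skip = skip, info = info, m = raw$m),
            class = "mixirt_recoded")
}
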