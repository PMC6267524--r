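#' Item parameters for the two measurement models
#'
#' Container for the item parameters of the two-class mixture model. Each of
#' the K items carries two parameter families:
#' \describe{
#'   \item{gPCM-m family (`R`)}{slope `alpha_R[i] > 0` and m category
#'     intercepts `beta_R[i, ]` with `beta_R[i, 1] == 0` for identification.}
#'   \item{IRTree family}{a 2PL skip node with slope `alpha_S[i] > 0` and
#'     intercept `beta_S[i]`, and an informative gPCM-(m-1) node with slope
#'     `alpha_T[i] > 0` and `m - 1` intercepts `beta_T[i, ]`,
#'     `beta_T[i, 1] == 0`.}
#' }
#' The canonical parameterization is slope + intercepts, `beta = -alpha *
#' delta`, because the sampler operates on intercepts (their posteriors are
#' more stable than those of the thresholds). Thresholds/locations are a
#' derived view, see [intercepts_to_thresholds()].
#'
#' @param alpha_R,alpha_S,alpha_T positive slope vectors of length K.
#' @param beta_R K x m intercept matrix, first column zero.
#' @param beta_S length-K skip intercept vector.
#' @param beta_T K x (m-1) intercept matrix, first column zero.
#' @param m number of raw response categories (odd, >= 3).
#' @return Object of class `mixirt_items`.
#' @export
item_params <- function(alpha_R, beta_R, alpha_S, beta_S, alpha_T, beta_T, m) {
  m <- as.integer(m)
  beta_R <- rbind(beta_R)
  beta_T <- rbind(beta_T)
  K <- length(alpha_R)
  if (nrow(beta_R) != K || length(alpha_S) != K || length(beta_S) != K ||
      length(alpha_T) != K || nrow(beta_T) != K) {
    stop("item parameter families disagree on the number of items")
  }
  if (ncol(beta_R) != m) stop("`beta_R` must have m = ", m, " columns")
  if (ncol(beta_T) != m - 1L) stop("`beta_T` must have m - 1 = ", m - 1L, " columns")
  if (any(alpha_R <= 0) || any(alpha_S <= 0) || any(alpha_T <= 0)) {
    stop("all slopes must be strictly positive")
  }
  if (any(beta_R[, 1L] != 0) || any(beta_T[, 1L] != 0)) {
    stop("first intercepts are fixed at zero for identification")
  }
  structure(
    list(alpha_R = as.numeric(alpha_R), beta_R = unname(beta_R),
         alpha_S = as.numeric(alpha_S), beta_S = as.numeric(beta_S),
         alpha_T = as.numeric(alpha_T), beta_T = unname(beta_T),
         m = m, n_items = K),
    class = "mixirt_items"
  )
}

#' @export
print.mixirt_items <- function(x, ...) {
  cat(sprintf("mixture item parameters: %d items, m = %d\n", x$n_items, x$m))
  cat(sprintf("gPCM-%d slopes in [%.2f, %.2f]; skip slopes in [%.2f, %.2f]\n",
              x$m, min(x$alpha_R), max(x$alpha_R),
              min(x$alpha_S), max(x$alpha_S)))
  invisible(x)
}

#' Convert between threshold and intercept parameterizations
#'
#' Category intercepts and thresholds are linked by `beta = -alpha * delta`.
#' The first threshold/intercept is the identification constraint and stays
#' exactly zero under either view.
#'
#' @param slope positive item slope (scalar or vector, recycled rowwise).
#' @param thresholds,intercepts numeric vector or matrix (items in rows).
#' @return The converted vector/matrix.
#' @export
thresholds_to_intercepts <- function(slope, thresholds) {
  if (is.matrix(thresholds)) -thresholds * slope else -slope * thresholds
}

#' @rdname thresholds_to_intercepts
#' @export
intercepts_to_thresholds <- function(slope, intercepts) {
  if (is.matrix(intercepts)) -intercepts / slope else -intercepts / slope
}

#' Person state: latent traits and class membership
#'
#' @param theta N x (D+1) matrix of latent traits. Column 1 is the skip
#'   trait `theta_0` (tendency to choose the noninformative middle
#'   category); columns `2..D+1` are the substantive traits `theta_1..theta_D`.
#' @param z integer vector of class indicators: 1 = gPCM-m class,
#'   0 = IRTree class.
#' @return Object of class `mixirt_persons`.
#' @export
person_state <- function(theta, z) {
  theta <- rbind(theta)
  z <- as.integer(z)
  if (nrow(theta) != length(z)) stop("`theta` and `z` disagree on N")
  if (ncol(theta) < 2L) stop("`theta` needs at least 2 columns (theta_0 plus one trait)")
  if (any(!z %in% c(0L, 1L))) stop("class indicators must be 0 (IRTree) or 1 (gPCM)")
  structure(list(theta = unname(theta), z = z,
                 n_persons = length(z), n_dims = ncol(theta) - 1L),
            class = "mixirt_persons")
}
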