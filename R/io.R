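#' Read a wide CSV of Likert responses
#'
#' The expected layout is one header row of item identifiers and one row
#' per person, integer cells; empty cells are missing responses. The
#' category count is validated against `m` when given, otherwise inferred
#' as the maximum observed score (which must be odd).
#'
#' @param path CSV file path.
#' @param m number of categories, or `NULL` to infer.
#' @param missing_code token (besides the empty cell) treated as missing.
#' @return A [response_matrix()] object; item identifiers are kept as
#'   column names.
#' @export
read_responses <- function(path, m = NULL, missing_code = "") {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = c("NA", missing_code),
                        colClasses = "character")
  if (anyDuplicated(names(df))) {
    stop("duplicate item identifiers in ", path, ": ",
         paste(names(df)[duplicated(names(df))], collapse = ", "))
  }
  x <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  x <- matrix(x, nrow = nrow(df), dimnames = list(NULL, names(df)))
  bad_cell <- which(is.na(x) & !is.na(as.matrix(df)) &
                      as.matrix(df) != missing_code, arr.ind = TRUE)
  if (nrow(bad_cell) > 0L) {
    stop(sprintf("non-numeric cell at row %d, column '%s'",
                 bad_cell[1L, 1L], names(df)[bad_cell[1L, 2L]]))
  }
  if (any(!is.na(x) & x != round(x))) stop("scores must be integers")
  response_matrix(x, m)
}

#' Read an item-to-dimension design file
#'
#' Two-column CSV (`item_id`, `dimension`). When `item_ids` is supplied
#' (e.g. the column names of the response matrix) the rows are matched and
#' reordered accordingly.
#'
#' @param path CSV file path.
#' @param item_ids optional item identifiers defining the column order.
#' @return A [test_design()] vector.
#' @export
read_design <- function(path, item_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("design file needs columns (item_id, dimension)")
  names(df)[1:2] <- c("item_id", "dimension")
  if (!is.null(item_ids)) {
    idx <- match(item_ids, df$item_id)
    if (anyNA(idx)) {
      stop("design file is missing items: ",
           paste(item_ids[is.na(idx)], collapse = ", "))
    }
    df <- df[idx, ]
  }
  test_design(df$dimension)
}

#' Write a response matrix (and optional truth files) to CSV
#'
#' @param data a [response_matrix()] object.
#' @param path output CSV path.
#' @export
write_responses <- function(data, path) {
  x <- data$scores
  if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a fitted model to disk
#'
#' Writes, under `dir`: per-chain draw tables (`chain<k>_draws.csv`, one
#' row per retained iteration with labeled columns for all item
#' parameters, `pi`, `Sigma` and the log-likelihood), a person summary
#' (`persons.csv`: posterior-mean traits, class probability, assignment),
#' an item summary (`items.csv`), and a JSON `manifest.json` holding the
#' resolved configuration, seeds, per-chain `L_c` and the selected chain --
#' enough to replay the run.
#'
#' @param fit a `mixirt_fit` object.
#' @param dir output directory (created if needed).
#' @param chains which chains' draws to write (default: the selected one).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir, chains = fit$best_chain) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cc in chains) {
    utils::write.csv(draws_table(fit$chains[[cc]]),
                     file.path(dir, sprintf("chain%d_draws.csv", cc)),
                     row.names = FALSE)
  }
  sm <- fit$summary
  D1 <- ncol(sm$theta)
  persons <- data.frame(person = seq_len(nrow(sm$theta)))
  colnames_theta <- paste0("theta", 0:(D1 - 1L))
  for (j in seq_len(D1)) persons[[colnames_theta[j]]] <- sm$theta[, j]
  persons$class_prob_gpcm <- sm$class_prob
  persons$assignment <- sm$assignment
  utils::write.csv(persons, file.path(dir, "persons.csv"), row.names = FALSE)

  it <- sm$items
  items_df <- data.frame(item = seq_len(it$n_items), alpha_R = it$alpha_R,
                         alpha_S = it$alpha_S, beta_S = it$beta_S,
                         alpha_T = it$alpha_T)
  for (k in seq_len(it$m)) items_df[[paste0("beta_R", k)]] <- it$beta_R[, k]
  for (k in seq_len(it$m - 1L)) items_df[[paste0("beta_T", k)]] <- it$beta_T[, k]
  utils::write.csv(items_df, file.path(dir, "items.csv"), row.names = FALSE)

  manifest <- list(
    model = fit$model,
    n_chains = length(fit$chains),
    n_iter = fit$config$n_iter, n_burnin = fit$config$n_burnin,
    seed = fit$config$seed,
    chain_seeds = vapply(seq_along(fit$chains),
                         function(cc) chain_seed(fit$config$seed, cc),
                         integer(1L)),
    L_c = fit$L_c, best_chain = fit$best_chain,
    design = fit$design, pi_mean = fit$summary$pi)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# flat per-iteration table of one chain's item/global draws
draws_table <- function(draws) {
  m <- draws$m
  K <- ncol(draws$alpha_R)
  out <- data.frame(iteration = seq_len(draws$n_retained))
  for (i in seq_len(K)) {
    out[[sprintf("alpha_R.%d", i)]] <- draws$alpha_R[, i]
    for (k in 2:m) out[[sprintf("beta_R.%d.%d", i, k)]] <- draws$beta_R[, i, k]
    out[[sprintf("alpha_S.%d", i)]] <- draws$alpha_S[, i]
    out[[sprintf("beta_S.%d", i)]] <- draws$beta_S[, i]
    out[[sprintf("alpha_T.%d", i)]] <- draws$alpha_T[, i]
    for (k in 2:(m - 1L)) {
      out[[sprintf("beta_T.%d.%d", i, k)]] <- draws$beta_T[, i, k]
    }
  }
  D1 <- dim(draws$sigma)[2L]
  for (a in seq_len(D1)) for (b in a:D1) {
    out[[sprintf("sigma.%d.%d", a, b)]] <- draws$sigma[, a, b]
  }
  out$pi <- draws$pi
  out$loglik <- draws$loglik
  out
}
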