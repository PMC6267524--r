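#' Classification accuracy of the latent classes
#'
#' The outcome measures of the classification study:
#' \describe{
#'   \item{p_all}{overall proportion of persons whose posterior-mode class
#'     equals the generating class;}
#'   \item{p_tree, p_pcm}{the same proportion restricted to persons whose
#'     true class is IRTree / gPCM (reported as `NA` when the restriction is
#'     empty);}
#'   \item{p_cert}{proportion of persons both correctly classified and with
#'     posterior probability of the true class of at least .95.}
#' }
#'
#' @param true_class integer vector of generating class indicators
#'   (1 = gPCM, 0 = IRTree).
#' @param summary a [summarize_posterior()] result (or any list with
#'   `assignment` and `class_prob`, the latter being P(gPCM class)).
#' @return Object of class `mixirt_classification` with the four
#'   proportions and `n_tree` / `n_pcm` counts.
#' @export
classification_metrics <- function(true_class, summary) {
  true_class <- as.integer(true_class)
  if (length(true_class) != length(summary$assignment)) {
    stop("`true_class` and the posterior summary disagree on N")
  }
  correct <- summary$assignment == true_class
  prob_true <- ifelse(true_class == 1L, summary$class_prob,
                      1 - summary$class_prob)
  sub_mean <- function(v, keep) if (any(keep)) mean(v[keep]) else NA_real_
  structure(
    list(p_all = mean(correct),
         p_tree = sub_mean(correct, true_class == 0L),
         p_pcm = sub_mean(correct, true_class == 1L),
         p_cert = mean(correct & prob_true >= 0.95),
         n_tree = sum(true_class == 0L), n_pcm = sum(true_class == 1L)),
    class = "mixirt_classification"
  )
}

#' @export
print.mixirt_classification <- function(x, ...) {
  cat(sprintf("P_all = %.3f, P_Tree = %s, P_PCM = %s, P_cert = %.3f\n",
              x$p_all,
              ifelse(is.na(x$p_tree), "NA", sprintf("%.3f", x$p_tree)),
              ifelse(is.na(x$p_pcm), "NA", sprintf("%.3f", x$p_pcm)),
              x$p_cert))
  invisible(x)
}

#' Bias, variance and MSE of parameter estimates across replications
#'
#' For each scalar parameter: `bias = mean(est) - truth`, `variance` is the
#' across-replication variance in its population form (divide by the number
#' of replications, so that `MSE = bias^2 + variance` holds exactly per
#' scalar), and `MSE = mean((est - truth)^2)`. Family summaries average the
#' absolute bias, the variance and the MSE over the family's scalars.
#' Identification-fixed entries (first category intercepts) are excluded --
#' they are constraints, not estimates.
#'
#' @param truth named list of numeric vectors/matrices of generating values
#'   (e.g. `alpha_R`, `beta_R`, ..., `theta1`).
#' @param estimates list of replications; each a named list with the same
#'   structure as `truth`.
#' @return Object of class `mixirt_recovery`: a data frame with one row per
#'   family (`bias`, `variance`, `mse`, `n_params`, `n_replications`), plus
#'   per-scalar arrays in attribute `"per_scalar"`.
#' @export
recovery_metrics <- function(truth, estimates) {
  if (length(estimates) < 1L) stop("need at least one replication")
  fams <- names(truth)
  per_scalar <- list()
  rows <- lapply(fams, function(f) {
    tr <- as.numeric(truth[[f]])
    est <- do.call(rbind, lapply(estimates, function(e) as.numeric(e[[f]])))
    if (ncol(est) != length(tr)) stop("estimate/truth length mismatch for ", f)
    free <- free_param_mask(f, truth[[f]])
    tr <- tr[free]; est <- est[, free, drop = FALSE]
    R <- nrow(est)
    bias <- colMeans(est) - tr
    vr <- colMeans(est^2) - colMeans(est)^2      # population form
    mse <- colMeans(sweep(est, 2L, tr)^2)
    per_scalar[[f]] <<- list(bias = bias, variance = vr, mse = mse)
    data.frame(family = f, bias = mean(abs(bias)), variance = mean(vr),
               mse = mean(mse), n_params = length(tr), n_replications = R,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_scalar") <- per_scalar
  class(out) <- c("mixirt_recovery", class(out))
  out
}

# first-category intercepts are fixed at 0 for identification and are not
# estimated; drop them from recovery summaries
free_param_mask <- function(family, truth_value) {
  if (is.matrix(truth_value) && family %in% c("beta_R", "beta_T")) {
    mask <- matrix(TRUE, nrow(truth_value), ncol(truth_value))
    mask[, 1L] <- FALSE
    as.vector(mask)
  } else {
    rep(TRUE, length(truth_value))
  }
}

#' Average squared error of posterior-mean trait estimates
#'
#' Person-level MSE of the primary substantive trait within one fitted data
#' set: the average over persons of `(posterior mean - truth)^2`.
#'
#' @param fit a `mixirt_fit` object (or a `mixirt_summary`).
#' @param truth a [person_state()] object with generating values.
#' @param dim substantive dimension (1-based; column `dim + 1` of `theta`).
#' @param subset optional logical/integer person subset (e.g. the true
#'   IRTree class).
#' @return Mean squared error over the selected persons.
#' @export
theta_mse <- function(fit, truth, dim = 1L, subset = NULL) {
  sm <- if (inherits(fit, "mixirt_fit")) fit$summary else fit
  err <- sm$theta[, dim + 1L] - truth$theta[, dim + 1L]
  if (!is.null(subset)) err <- err[subset]
  mean(err^2)
}

#' Deviance information criterion of a fit
#'
#' `D_bar` is the deviance (`-2 log L`) averaged over retained iterations,
#' each evaluated at that iteration's sampled parameters including the
#' sampled class indicators; it is recovered directly from the stored
#' per-iteration log-likelihoods. `D_hat` is the deviance at the posterior
#' summary (posterior means, posterior-mode class indicators). The
#' effective number of parameters is `p_D = D_bar - D_hat` and
#' `DIC = D_bar + p_D = 2 D_bar - D_hat`.
#'
#' @param fit a `mixirt_fit` object, or a `mixirt_draws` object together
#'   with `data`/`design`.
#' @param data the [response_matrix()] the model was fitted to.
#' @param design a [test_design()] vector.
#' @return Object of class `mixirt_dic` with `mean_deviance`,
#'   `plugin_deviance`, `p_d` and `dic`.
#' @export
compute_dic <- function(fit, data, design) {
  if (inherits(fit, "mixirt_fit")) {
    draws <- fit$draws
    sm <- fit$summary
  } else {
    draws <- fit
    sm <- summarize_posterior(draws)
  }
  d_bar <- mean(-2 * draws$loglik)
  persons <- person_state(sm$theta, sm$assignment)
  d_hat <- total_deviance(data, sm$items, persons, design)
  structure(list(mean_deviance = d_bar, plugin_deviance = d_hat,
                 p_d = d_bar - d_hat, dic = 2 * d_bar - d_hat),
            class = "mixirt_dic")
}

#' @export
print.mixirt_dic <- function(x, ...) {
  cat(sprintf("D_bar = %.2f, p_D = %.2f, DIC = %.2f\n",
              x$mean_deviance, x$p_d, x$dic))
  invisible(x)
}

#' Run a replication study over a grid of simulation designs
#'
#' For each design and replication: simulate a data set, fit the mixture
#' model (optionally also the two nonmixture models), and compute
#' classification metrics and trait-recovery summaries. Returns a
#' long-format table, one row per (condition, replication, metric).
#' Per-replication seeds derive from each design's `base_seed`, so results
#' are reproducible and independent of execution order.
#'
#' @param designs list of [sim_design()] objects (or a single one).
#' @param prior a [prior_config()] object or `NULL` (per-design default).
#' @param config a [chain_config()] object.
#' @param fit_nonmixture_models also fit the gpcm and irtree nonmixture
#'   models to every replication.
#' @param verbose print progress.
#' @return A long-format `data.frame` with columns `n_persons`, `n_items`,
#'   `n_dims`, `tree_fraction`, `replication`, `metric`, `value`.
#' @export
run_study <- function(designs, prior = NULL, config = chain_config(),
                      fit_nonmixture_models = FALSE, verbose = FALSE) {
  if (inherits(designs, "mixirt_simdesign")) designs <- list(designs)
  rows <- list()
  add <- function(sd, r, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      n_persons = sd$n_persons, n_items = sd$n_items, n_dims = sd$n_dims,
      tree_fraction = sd$tree_fraction, replication = r,
      metric = metric, value = value, stringsAsFactors = FALSE)
  }
  for (sd in designs) {
    pr <- if (is.null(prior)) prior_config(sd$n_dims) else prior
    for (r in seq_len(sd$n_replications)) {
      res <- tryCatch({
        dat <- simulate_mixture_data(sd, r)
        cfg <- config
        cfg$seed <- chain_seed(config$seed, 1000L * r)
        fit <- fit_mixture(dat$responses, dat$design, pr, cfg)
        if (sd$tree_fraction > 0) {
          cm <- classification_metrics(dat$persons$z, fit$summary)
          add(sd, r, "p_all", cm$p_all); add(sd, r, "p_tree", cm$p_tree)
          add(sd, r, "p_pcm", cm$p_pcm); add(sd, r, "p_cert", cm$p_cert)
        } else {
          add(sd, r, "empty_tree_class",
              as.numeric(sum(fit$summary$assignment == 0L) == 0L))
        }
        add(sd, r, "theta1_mse_mixture", theta_mse(fit, dat$persons))
        if (fit_nonmixture_models) {
          for (mod in c("gpcm", "irtree")) {
            nf <- fit_nonmixture(dat$responses, dat$design, mod, pr, cfg)
            add(sd, r, paste0("theta1_mse_", mod), theta_mse(nf, dat$persons))
          }
        }
        TRUE
      }, error = function(e) e)
      if (inherits(res, "error")) {
        add(sd, r, "failed", 1)
        if (verbose) message(sprintf("replication %d failed: %s", r,
                                     conditionMessage(res)))
      } else if (verbose) {
        message(sprintf("design N=%d K=%d P=%.2f replication %d done",
                        sd$n_persons, sd$n_items, sd$tree_fraction, r))
      }
    }
  }
  do.call(rbind, rows)
}

#' Post-hoc per-class model comparison
#'
#' Splits the persons by their mixture-model class assignment and fits both
#' nonmixture models (gPCM-m and IRTree) to each subset, comparing them by
#' DIC. If each class really follows its own measurement model, the DIC
#' should prefer a different model in each class.
#'
#' @param data a [response_matrix()] object.
#' @param design a [test_design()] vector.
#' @param summary a [summarize_posterior()] result with the class
#'   assignments.
#' @param prior a [prior_config()] object.
#' @param config a [chain_config()] object.
#' @return Data frame with one row per (class, model): `class`, `model`,
#'   `mean_deviance`, `p_d`, `dic` (`NA` rows for an empty class).
#' @export
per_class_posthoc <- function(data, design, summary,
                              prior = prior_config(n_dims(design)),
                              config = chain_config()) {
  rows <- list()
  for (cls in c(0L, 1L)) {
    keep <- summary$assignment == cls
    for (mod in c("gpcm", "irtree")) {
      if (!any(keep)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cls, model = mod, mean_deviance = NA_real_,
          p_d = NA_real_, dic = NA_real_, stringsAsFactors = FALSE)
        next
      }
      sub <- response_matrix(data$scores[keep, , drop = FALSE], data$m)
      fit <- fit_nonmixture(sub, design, mod, prior, config)
      dic <- compute_dic(fit, sub, design)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, model = mod, mean_deviance = dic$mean_deviance,
        p_d = dic$p_d, dic = dic$dic, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
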