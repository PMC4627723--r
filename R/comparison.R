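# Accept the long evidence tibble from evidence_table() or a
# subjects x models matrix; returns the matrix with model columns.
evidence_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(colnames(table))) {
      colnames(table) <- sprintf("model%d", seq_len(ncol(table)))
    }
    return(table)
  }
  stopifnot(is.data.frame(table),
            all(c("subject", "model", "log_evidence") %in% names(table)))
  wide <- tidyr::pivot_wider(as_tibble(table)[c("subject", "model", "log_evidence")],
                             names_from = "model", values_from = "log_evidence")
  m <- as.matrix(wide[setdiff(names(wide), "subject")])
  rownames(m) <- wide$subject
  if (anyNA(m) || any(!is.finite(m))) {
    abort("evidence table must be complete and finite",
          class = "confbms_error_invalid_input")
  }
  m
}

#' Fixed-effects posterior over models
#'
#' Assumes every subject uses the same model: the group posterior is
#' proportional to the model prior times the product of per-subject
#' evidences, i.e. the exponential of the column-summed log evidence.
#' Computed with a max shift so it never underflows.
#'
#' @param table A tidy evidence table from [evidence_table()] (columns
#'   `subject`, `model`, `log_evidence`) or a subjects x models matrix.
#' @param model_prior Optional prior probabilities per model (default
#'   uniform).
#' @return A tibble with columns `model`, `total_log_evidence`, `posterior`.
#' @export
fixed_effects_posterior <- function(table, model_prior = NULL) {
  m <- evidence_matrix(table)
  K <- ncol(m)
  if (is.null(model_prior)) model_prior <- rep(1 / K, K)
  if (length(model_prior) != K || any(model_prior < 0) ||
      abs(sum(model_prior) - 1) > 1e-8) {
    abort("`model_prior` must be a probability distribution over the models",
          class = "confbms_error_invalid_parameter")
  }
  total <- colSums(m)
  lp <- total + log(model_prior)
  post <- exp(lp - max(lp))
  tibble(model = colnames(m), total_log_evidence = unname(total),
         posterior = unname(post / sum(post)))
}

#' Random-effects Bayesian model selection with exceedance probabilities
#'
#' Treats the model used by each subject as a random effect: model
#' frequencies in the population carry a Dirichlet prior, each subject's
#' model is drawn from those frequencies, and the per-subject evidences
#' enter as likelihoods. The posterior over frequencies is approximated with
#' the standard variational fixed point (per-subject responsibilities
#' weighted by digamma terms of the current Dirichlet, concentrations
#' updated by summed responsibilities), iterated to convergence. Exceedance
#' probabilities — the posterior probability that each model is the most
#' frequent — are estimated by Monte-Carlo draws from the converged
#' Dirichlet.
#'
#' @inheritParams fixed_effects_posterior
#' @param alpha0 Prior Dirichlet concentration(s), scalar or per model
#'   (default 1).
#' @param n_exceedance_draws Dirichlet draws for the exceedance estimate.
#' @param seed Optional integer seed for the exceedance draws.
#' @param max_iter,tol Convergence controls on the concentration update.
#' @return An object of class `bms_result` with elements `alpha`,
#'   `expected_freq`, `exceedance`, `responsibilities`, `n_iter`.
#' @export
random_effects_bms <- function(table, alpha0 = 1, n_exceedance_draws = 1e5,
                               seed = NULL, max_iter = 1000, tol = 1e-6) {
  m <- evidence_matrix(table)
  K <- ncol(m)
  alpha0 <- rep_len(alpha0, K)
  if (any(alpha0 <= 0)) {
    abort("`alpha0` must be positive", class = "confbms_error_invalid_parameter")
  }
  alpha <- alpha0 + nrow(m) / K
  g <- NULL
  for (it in seq_len(max_iter)) {
    lg <- sweep(m, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- alpha0 + colSums(g)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) break
    if (it == max_iter) {
      abort(sprintf("random-effects BMS did not converge in %d iterations (last change %.2e)",
                    max_iter, delta),
            class = "confbms_error_convergence")
    }
  }
  draws <- with_substream(seed, "exceedance", code = {
    gmat <- matrix(rgamma(n_exceedance_draws * K, shape = rep(alpha, each = n_exceedance_draws)),
                   ncol = K)
    tabulate(max.col(gmat, ties.method = "first"), nbins = K)
  })
  structure(list(alpha = setNames(alpha, colnames(m)),
                 expected_freq = setNames(alpha / sum(alpha), colnames(m)),
                 exceedance = setNames(draws / sum(draws), colnames(m)),
                 responsibilities = g,
                 n_iter = it, models = colnames(m), alpha0 = alpha0),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result> random-effects model comparison\n")
  print(round(rbind(alpha = x$alpha, expected_freq = x$expected_freq,
                    exceedance = x$exceedance), 4))
  invisible(x)
}

#' Two-sided one-sample t-test on per-subject log-evidence differences
#'
#' Tests whether the mean per-subject log-evidence difference between two
#' models is zero, using the classical one-sample t-test with `n - 1`
#' degrees of freedom.
#'
#' @param diffs Numeric vector of per-subject differences (length at least
#'   2, nonzero variance).
#' @return A one-row tibble with `estimate`, `statistic`, `df`, `p_value`,
#'   `conf_low`, `conf_high`.
#' @export
loglik_diff_test <- function(diffs) {
  if (!is.numeric(diffs) || length(diffs) < 2L || anyNA(diffs)) {
    abort("`diffs` must be at least two finite values",
          class = "confbms_error_invalid_input")
  }
  if (stats::var(diffs) == 0) {
    abort("`diffs` has zero variance", class = "confbms_error_invalid_input")
  }
  ht <- stats::t.test(diffs, mu = 0, alternative = "two.sided")
  tibble(estimate = unname(ht$estimate), statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2])
}
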