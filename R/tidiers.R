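#' Tidy an evidence estimate into its per-run values
#'
#' @param x An `evidence_estimate` from [importance_evidence()] or
#'   [naive_evidence()].
#' @param ... Unused.
#' @return A tibble with one row per run: `run`, `log_evidence`,
#'   `se_within`, `sigma_mean`, `n_degenerate`, `kept`.
#' @method tidy evidence_estimate
#' @export
tidy.evidence_estimate <- function(x, ...) {
  as_tibble(x$per_run)
}

#' One-row summary of an evidence estimate
#'
#' @inheritParams tidy.evidence_estimate
#' @return A one-row tibble: `model`, `method`, `log_evidence`,
#'   `std_error`, `sigma_posterior_mean`, `n_is_samples`, `n_runs`.
#' @method glance evidence_estimate
#' @export
glance.evidence_estimate <- function(x, ...) {
  tibble(model = x$model, method = x$method,
         log_evidence = x$log_evidence, std_error = x$std_error,
         sigma_posterior_mean = x$sigma_posterior_mean,
         n_is_samples = x$n_is_samples, n_runs = x$n_runs)
}

#' Tidy a random-effects model-comparison result
#'
#' @param x A `bms_result` from [random_effects_bms()].
#' @param ... Unused.
#' @return A tibble with one row per model: `model`, `alpha`,
#'   `expected_freq`, `exceedance`.
#' @method tidy bms_result
#' @export
tidy.bms_result <- function(x, ...) {
  tibble(model = x$models, alpha = unname(x$alpha),
         expected_freq = unname(x$expected_freq),
         exceedance = unname(x$exceedance))
}

#' One-row summary of a random-effects comparison
#'
#' @inheritParams tidy.bms_result
#' @return A one-row tibble: `n_models`, `n_subjects`, `n_iter`,
#'   `best_model`, `best_exceedance`.
#' @method glance bms_result
#' @export
glance.bms_result <- function(x, ...) {
  best <- which.max(x$exceedance)
  tibble(n_models = length(x$models),
         n_subjects = nrow(x$responsibilities),
         n_iter = x$n_iter,
         best_model = x$models[best],
         best_exceedance = unname(x$exceedance[best]))
}
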