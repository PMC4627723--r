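#' Experimental design of the two-interval contrast-discrimination study
#'
#' The study design being emulated: 480 experimental trials, a target in one
#' of two intervals, four added-contrast levels on a 0.10 baseline, and a
#' 1-6 confidence scale. The baseline contrast is metadata only — the model
#' operates on the added-contrast scale.
#'
#' @param n_trials Number of trials (default 480).
#' @param contrasts Added-contrast set.
#' @param baseline_contrast Baseline Gabor contrast (metadata).
#' @param balanced If `TRUE` (default) every (interval, contrast) condition
#'   appears equally often, which requires `n_trials` divisible by twice the
#'   number of contrasts.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(n_trials = 480, contrasts = default_contrasts(),
                              baseline_contrast = 0.10, balanced = TRUE) {
  check_contrast_set(contrasts)
  if (n_trials < 1) {
    abort("`n_trials` must be positive", class = "confbms_error_invalid_parameter")
  }
  ncond <- 2L * length(contrasts)
  if (balanced && n_trials %% ncond != 0) {
    abort(sprintf("balanced design needs `n_trials` divisible by %d", ncond),
          class = "confbms_error_invalid_parameter")
  }
  structure(list(n_trials = as.integer(n_trials), contrasts = sort(contrasts),
                 baseline_contrast = baseline_contrast, balanced = balanced),
            class = "experiment_design")
}

#' Generate the trial sequence of an experiment
#'
#' Balanced mode places each (interval, contrast) condition exactly
#' `n_trials / (2 * n_contrasts)` times in random order; unbalanced mode
#' samples conditions independently and uniformly.
#'
#' @param design An [experiment_design()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `trial`, `interval`, `contrast`.
#' @export
#' @examples
#' dplyr::count(design_trials(experiment_design(), seed = 1), interval, contrast)
design_trials <- function(design = experiment_design(), seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- condition_grid(design$contrasts)
  idx <- with_substream(seed, "design", code = {
    if (design$balanced) {
      sample(rep(seq_len(nrow(grid)), each = design$n_trials / nrow(grid)))
    } else {
      sample.int(nrow(grid), design$n_trials, replace = TRUE)
    }
  })
  tibble(trial = seq_len(design$n_trials),
         interval = grid$interval[idx], contrast = grid$contrast[idx])
}

#' Reference subject parameter settings
#'
#' `"figure8"` gives the fixed, representative parameter setting used for
#' the theoretical model-contrast figures: `sigma = 0.07`, no lapses, and a
#' uniform response-probability matrix (`p[d, c] = 1/12`). `"random"` draws
#' a parameter set from the prior.
#'
#' @param style `"figure8"` or `"random"`.
#' @param seed Seed for the random style.
#' @param prior Prior used by the random style.
#' @return A [subject_params()] object.
#' @export
default_subject_params <- function(style = c("figure8", "random"), seed = NULL,
                                   prior = prior_spec()) {
  style <- match.arg(style)
  if (style == "figure8") {
    subject_params(0.07, 0, matrix(1 / 12, 2, 6))
  } else {
    draw <- sample_prior(1, prior, seed = seed)
    subject_params(draw$sigma[1], draw$lapse[1], draw$p[[1]])
  }
}

#' Simulate a full synthetic subject
#'
#' Calibrates the subject's thresholds once from their response
#' probabilities, then simulates every trial: a fresh sensory draw, a
#' decision by thresholding the decision variable, and a confidence report
#' by binning the confidence variable. With probability `lapse` a trial's
#' decision and confidence are replaced by a uniform draw over the 12
#' response cells (the discrete-event view of the lapse mixture).
#'
#' @inheritParams response_cell_table
#' @param conditions Trial conditions, e.g. from [design_trials()] (columns
#'   `interval`, `contrast`).
#' @param n_calibration Pool samples per condition for threshold
#'   calibration.
#' @return A trial tibble with columns `trial`, `interval`, `contrast`,
#'   `decision`, `confidence`.
#' @export
#' @examples
#' simulate_subject("bayes", default_subject_params("figure8"),
#'                  design_trials(experiment_design(n_trials = 8), seed = 1),
#'                  n_calibration = 1000, seed = 1)
simulate_subject <- function(model, params, conditions,
                             n_calibration = 12500, seed = NULL,
                             contrasts = default_contrasts(),
                             min_branch = 100) {
  check_model(model)
  stopifnot(inherits(params, "subject_params"))
  pool <- build_sample_pool(model, params$sigma, contrasts, n_calibration,
                            seed = if (is.null(seed)) NULL else substream_seed(seed, "calibration"))
  thresholds <- calibrate_thresholds(pool, params$response_probs, min_branch)
  draws <- sample_sensory(conditions, params$sigma, n = 1,
                          seed = if (is.null(seed)) NULL else substream_seed(seed, "trials"))
  resp <- assign_responses(draws$x1, draws$x2, model, thresholds,
                           params$sigma, sort(contrasts))
  k <- nrow(draws)
  lapses <- with_substream(seed, "lapse", code = {
    is_lapse <- runif(k) < params$lapse
    list(is_lapse = is_lapse,
         d = sample(1:2, k, replace = TRUE),
         c = sample(1:6, k, replace = TRUE))
  })
  decision <- ifelse(lapses$is_lapse, lapses$d, resp$decision)
  confidence <- ifelse(lapses$is_lapse, lapses$c, resp$confidence)
  tibble(trial = seq_len(k),
         interval = as.integer(draws$interval), contrast = draws$contrast,
         decision = as.integer(decision), confidence = as.integer(confidence))
}
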