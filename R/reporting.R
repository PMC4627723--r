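#' Signed confidence: one axis for decision and confidence
#'
#' Combines a decision and a confidence level into a single signed value
#' whose sign gives the decision (negative for interval 1, positive for
#' interval 2) and whose absolute value gives the confidence level.
#'
#' @param decision Integer vector of decisions (1 or 2).
#' @param confidence Integer vector of confidence levels (1..6).
#' @return An integer vector in `{-6..-1, 1..6}`.
#' @export
#' @examples
#' signed_confidence(c(1, 2), c(3, 3))
signed_confidence <- function(decision, confidence) {
  decision <- check_decision(decision)
  if (anyNA(confidence) || !all(confidence %in% 1:6)) {
    abort("confidence must be in 1..6", class = "confbms_error_invalid_parameter")
  }
  as.integer(ifelse(decision == 1L, -confidence, confidence))
}

#' Signed contrast: one axis for target interval and contrast
#'
#' @param interval Integer vector of target intervals (1 or 2).
#' @param contrast Positive contrast values.
#' @return A numeric vector, negative for interval 1, positive for
#'   interval 2.
#' @export
signed_contrast <- function(interval, contrast) {
  if (anyNA(interval) || !all(interval %in% c(1, 2))) {
    abort("interval must be 1 or 2", class = "confbms_error_invalid_parameter")
  }
  if (anyNA(contrast) || any(contrast <= 0)) {
    abort("contrast must be positive", class = "confbms_error_invalid_parameter")
  }
  ifelse(interval == 1, -contrast, contrast)
}

#' Theoretical signed-confidence distributions per condition
#'
#' The noise-free prediction of a model for the distribution over signed
#' confidence (decision sign times confidence level) in each stimulus
#' condition, derived from the Monte-Carlo response-cell table.
#'
#' @inheritParams response_cell_table
#' @return A tibble of class `confidence_distribution` with columns
#'   `interval`, `contrast`, `signed_contrast`, `signed_confidence`, `prob`
#'   (each condition's 12 probabilities sum to 1).
#' @export
theoretical_confidence_distributions <- function(model, params,
                                                 contrasts = default_contrasts(),
                                                 n_per_condition = 12500,
                                                 seed = NULL, min_branch = 100) {
  tab <- response_cell_table(model, params, contrasts, n_per_condition,
                             seed, min_branch)
  out <- as_tibble(tab)
  out$signed_confidence <- signed_confidence(out$decision, out$confidence)
  out$signed_contrast <- signed_contrast(out$interval, out$contrast)
  out <- out[order(out$interval, out$contrast, out$signed_confidence),
             c("interval", "contrast", "signed_contrast", "signed_confidence", "prob")]
  structure(out, class = c("confidence_distribution", class(as_tibble(out))),
            model = model, sigma = params$sigma, lapse = params$lapse)
}

#' Map sensory space to confidence regions
#'
#' Labels every point of an `(x1, x2)` grid with the decision and confidence
#' a calibrated model assigns to it, delineating the regions of sensory
#' space that map to each signed confidence level. The Difference model's
#' regions are diagonal bands (functions of `x2 - x1` only); the Max model's
#' boundaries are axis-aligned within each decision region; the Bayes
#' model's boundaries are curved.
#'
#' @inheritParams response_cell_table
#' @param x1,x2 Numeric grid coordinates (the grid is their cross product).
#' @param n_calibration Pool samples per condition for calibration.
#' @return A tibble of class `region_map` with columns `x1`, `x2`,
#'   `decision`, `confidence`, `signed_confidence`.
#' @export
confidence_region_map <- function(model, params,
                                  x1 = seq(-0.1, 0.25, length.out = 101),
                                  x2 = seq(-0.1, 0.25, length.out = 101),
                                  contrasts = default_contrasts(),
                                  n_calibration = 12500, seed = NULL,
                                  min_branch = 100) {
  check_model(model)
  stopifnot(inherits(params, "subject_params"))
  pool <- build_sample_pool(model, params$sigma, contrasts, n_calibration, seed)
  thresholds <- calibrate_thresholds(pool, params$response_probs, min_branch)
  grid <- tidyr::expand_grid(x1 = x1, x2 = x2)
  resp <- assign_responses(grid$x1, grid$x2, model, thresholds,
                           params$sigma, sort(contrasts))
  out <- tibble(x1 = grid$x1, x2 = grid$x2,
                decision = resp$decision, confidence = resp$confidence,
                signed_confidence = signed_confidence(resp$decision, resp$confidence))
  structure(out, class = c("region_map", class(as_tibble(out))),
            model = model, sigma = params$sigma, thresholds = thresholds,
            contrasts = sort(contrasts))
}

#' Configuration of a full analysis run
#'
#' Bundles every setting of the evidence-and-comparison pipeline. Defaults
#' mirror the reference analysis: 1000 importance samples, 10 runs, 12500
#' cell-table samples per condition (1e5 pooled), the Gamma(2, 0.05) noise
#' prior, the log10-uniform lapse prior and the flat Dirichlet response
#' prior.
#'
#' @param models Models to compare.
#' @param prior A [prior_spec()].
#' @param n_is_samples,n_runs,n_per_condition Importance-sampler settings.
#' @param seed Integer root seed; every random substream of the pipeline is
#'   derived from it, so a rerun with the same config is bit-identical.
#' @param contrasts Contrast set of the design.
#' @param output_dir Optional directory for result files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(models = c("difference", "max", "bayes"),
                       prior = prior_spec(), n_is_samples = 1000,
                       n_runs = 10, n_per_condition = 12500,
                       seed = 1, contrasts = default_contrasts(),
                       output_dir = NULL) {
  if (length(models) == 0L) {
    abort("`models` must be nonempty", class = "confbms_error_invalid_parameter")
  }
  for (m in models) check_model(m)
  if (n_is_samples < 1 || n_runs < 1 || n_per_condition < 1) {
    abort("sample counts must be positive", class = "confbms_error_invalid_parameter")
  }
  structure(list(models = models, prior = prior,
                 n_is_samples = as.integer(n_is_samples),
                 n_runs = as.integer(n_runs),
                 n_per_condition = as.integer(n_per_condition),
                 seed = as.integer(seed), contrasts = sort(contrasts),
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full evidence-and-comparison pipeline
#'
#' For each subject dataset computes the importance-sampled model evidence
#' under every configured model, then the fixed-effects posterior over
#' models and (when there is more than one subject and model) the
#' random-effects comparison with exceedance probabilities. When
#' `config$output_dir` is set, writes the evidence table (CSV) and a
#' hierarchical results bundle (YAML) there.
#'
#' @param config A [run_config()].
#' @param datasets Named list of trial tibbles, or a character vector of
#'   file paths readable by [read_dataset()].
#' @return A list with elements `evidence` (tidy table), `fixed_effects`,
#'   `bms` (or `NULL`), `per_run`, `config`, and `files` (paths written).
#' @export
run_pipeline <- function(config, datasets) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(datasets)) {
    paths <- datasets
    datasets <- lapply(paths, read_dataset, contrasts = config$contrasts)
    names(datasets) <- sub("\\.[^.]*$", "", basename(paths))
  }
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    names(datasets) <- sprintf("subject%02d", seq_along(datasets))
  }
  per_run <- list()
  ev <- purrr::map_dfr(names(datasets), function(subj) {
    purrr::map_dfr(config$models, function(m) {
      est <- tryCatch(
        importance_evidence(datasets[[subj]], m, config$prior,
                            config$n_is_samples, config$n_runs,
                            config$n_per_condition,
                            seed = substream_seed(config$seed, "subject", subj),
                            contrasts = config$contrasts),
        error = function(e) {
          abort(sprintf("evidence stage failed for subject '%s', model '%s': %s",
                        subj, m, conditionMessage(e)),
                class = "confbms_error_pipeline", parent = e)
        })
      per_run[[paste(subj, m, sep = ".")]] <<- est$per_run_values
      tibble(subject = subj, model = m, log_evidence = est$log_evidence,
             std_error = est$std_error,
             sigma_posterior_mean = est$sigma_posterior_mean)
    })
  })
  fixed <- fixed_effects_posterior(ev)
  bms <- if (length(datasets) > 1L && length(config$models) > 1L) {
    random_effects_bms(ev, seed = substream_seed(config$seed, "bms"))
  }
  results <- list(evidence = ev, fixed_effects = fixed, bms = bms,
                  per_run = per_run, config = config, files = character())
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    ev_path <- file.path(config$output_dir, "evidence.csv")
    readr::write_csv(ev, ev_path)
    bundle_path <- file.path(config$output_dir, "results.yaml")
    write_results_bundle(results, bundle_path)
    results$files <- c(ev_path, bundle_path)
  }
  results
}
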