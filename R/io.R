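#' Read a trial dataset from a delimited file
#'
#' The trial-table format is comma-delimited with a header
#' `trial,interval,contrast,decision,confidence`: one row per trial,
#' intervals and decisions coded 1/2, confidence 1-6, contrast as the
#' added-contrast value.
#'
#' @param path Path to the file.
#' @param contrasts Allowed contrast set; rows with other contrasts are a
#'   parse error.
#' @return A trial tibble.
#' @export
read_dataset <- function(path, contrasts = default_contrasts()) {
  if (!file.exists(path)) {
    abort(sprintf("dataset file not found: %s", path),
          class = "confbms_error_invalid_input")
  }
  dat <- readr::read_csv(path, col_types = readr::cols(
    trial = readr::col_integer(),
    interval = readr::col_integer(),
    contrast = readr::col_double(),
    decision = readr::col_integer(),
    confidence = readr::col_integer()
  ))
  required <- c("trial", "interval", "contrast", "decision", "confidence")
  if (!all(required %in% names(dat))) {
    abort(sprintf("dataset must have columns %s", paste(required, collapse = ", ")),
          class = "confbms_error_invalid_input")
  }
  validate_dataset(dat[required], contrasts)
}

validate_dataset <- function(dat, contrasts = default_contrasts()) {
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows) > 0L) {
      abort(sprintf("invalid %s in dataset row(s) %s", what,
                    paste(utils::head(rows, 5L), collapse = ", ")),
            class = "confbms_error_invalid_input")
    }
  }
  bad(!dat$interval %in% c(1L, 2L), "interval (must be 1 or 2)")
  bad(!dat$decision %in% c(1L, 2L), "decision (must be 1 or 2)")
  bad(!dat$confidence %in% 1:6, "confidence (must be 1..6)")
  bad(!dat$contrast %in% contrasts, "contrast (not in the contrast set)")
  as_tibble(dat)
}

#' Write a trial dataset to a delimited file
#'
#' @param dataset A trial tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  cols <- c("trial", "interval", "contrast", "decision", "confidence")
  stopifnot(all(cols %in% names(dataset)))
  readr::write_csv(as_tibble(dataset)[cols], path)
  invisible(path)
}

#' Write a hierarchical results bundle
#'
#' Serializes the outputs of [run_pipeline()] — per-subject, per-model,
#' per-run log evidences and standard errors, sample counts, the root seed,
#' and the group-level comparisons — as a plain hierarchical key-value
#' (YAML) text file.
#'
#' @param results A results list from [run_pipeline()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results_bundle <- function(results, path) {
  yaml::write_yaml(results_to_list(results), path)
  invisible(path)
}

results_to_list <- function(results) {
  ev <- results$evidence
  subjects <- lapply(split(ev, ev$subject), function(d) {
    models <- lapply(split(d, d$model), function(r) {
      out <- list(log_evidence = r$log_evidence, std_error = r$std_error,
                  sigma_posterior_mean = r$sigma_posterior_mean)
      runs <- results$per_run[[paste(r$subject, r$model, sep = ".")]]
      if (!is.null(runs)) out$per_run_log_evidence <- runs
      out
    })
    models
  })
  list(
    config = list(models = results$config$models,
                  n_is_samples = results$config$n_is_samples,
                  n_runs = results$config$n_runs,
                  n_per_condition = results$config$n_per_condition,
                  seed = results$config$seed,
                  contrasts = results$config$contrasts),
    subjects = subjects,
    fixed_effects = as.list(setNames(results$fixed_effects$posterior,
                                     results$fixed_effects$model)),
    random_effects = if (is.null(results$bms)) NULL else list(
      alpha = as.list(results$bms$alpha),
      expected_freq = as.list(results$bms$expected_freq),
      exceedance = as.list(results$bms$exceedance)
    )
  )
}
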