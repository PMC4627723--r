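#' Prior specification for subject parameters
#'
#' Priors used when marginalizing the trial likelihood over subject
#' parameters: a Gamma prior on the sensory noise `sigma` (density
#' proportional to `sigma * exp(-sigma / scale)` at the default shape 2,
#' scale 0.05, mean 0.10 contrast units), a log10-uniform prior on the lapse
#' rate over `[1e-3, 1e-1]`, and a flat Dirichlet prior over the 12 response
#' cells.
#'
#' @param sigma_shape,sigma_scale Gamma shape and scale for `sigma`.
#' @param lapse_log10_range Length-2 range of `log10(lapse)`.
#' @param dirichlet_concentration 2 x 6 matrix of Dirichlet concentrations
#'   for the response probabilities (default all 1: uniform over the
#'   simplex).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(sigma_shape = 2, sigma_scale = 0.05,
                       lapse_log10_range = c(-3, -1),
                       dirichlet_concentration = matrix(1, 2, 6)) {
  if (sigma_shape <= 0 || sigma_scale <= 0) {
    abort("Gamma shape and scale must be positive",
          class = "confbms_error_invalid_parameter")
  }
  if (length(lapse_log10_range) != 2L ||
      lapse_log10_range[1] >= lapse_log10_range[2]) {
    abort("`lapse_log10_range` must be an increasing pair",
          class = "confbms_error_invalid_parameter")
  }
  stopifnot(is.matrix(dirichlet_concentration),
            all(dim(dirichlet_concentration) == c(2L, 6L)))
  if (any(dirichlet_concentration <= 0)) {
    abort("Dirichlet concentrations must be positive",
          class = "confbms_error_invalid_parameter")
  }
  structure(list(sigma_shape = sigma_shape, sigma_scale = sigma_scale,
                 lapse_log10_range = lapse_log10_range,
                 dirichlet_concentration = dirichlet_concentration),
            class = "prior_spec")
}

#' Draw subject parameters from the prior
#'
#' @param n Number of draws.
#' @param prior A [prior_spec()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `sigma`, `lapse` and a list-column `p` of
#'   2 x 6 response-probability matrices.
#' @export
sample_prior <- function(n = 1, prior = prior_spec(), seed = NULL) {
  draws <- draw_prior_components(n, prior, seed)
  p <- lapply(seq_len(n), function(i) unflatten_cells(draws$pmat[i, ]))
  tibble(sigma = draws$sigma, lapse = draws$lapse, p = p)
}

# matrix-form prior draws (rows of `pmat` are flattened response matrices)
draw_prior_components <- function(n, prior, seed = NULL) {
  stopifnot(inherits(prior, "prior_spec"))
  conc <- flatten_cells(prior$dirichlet_concentration)
  with_substream(seed, "prior", code = {
    sigma <- rgamma(n, shape = prior$sigma_shape, scale = prior$sigma_scale)
    lapse <- 10^runif(n, prior$lapse_log10_range[1], prior$lapse_log10_range[2])
    g <- matrix(rgamma(n * 12L, shape = rep(conc, each = n)), nrow = n)
    list(sigma = sigma, lapse = lapse, pmat = g / rowSums(g))
  })
}

# log density of a Dirichlet distribution at p (both flattened length-12)
ddirichlet_log <- function(p, alpha) {
  sum((alpha - 1) * log(p)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

#' Response-count matrix of a dataset
#'
#' The number of trials on which the subject gave each (decision,
#' confidence) response, irrespective of trial type. These counts define the
#' Dirichlet proposal used by the importance sampler.
#'
#' @param dataset A trial tibble with columns `decision` and `confidence`.
#' @return A 2 x 6 integer matrix whose entries sum to the trial count.
#' @export
count_matrix <- function(dataset) {
  stopifnot(all(c("decision", "confidence") %in% names(dataset)))
  m <- table(factor(dataset$decision, levels = 1:2),
             factor(dataset$confidence, levels = 1:6))
  unflatten_cells(flatten_cells(matrix(as.integer(m), 2L, 6L)))
}

#' Log-likelihood of a dataset under a cell-probability table
#'
#' The trial likelihood factorizes over trials, so the log-likelihood is the
#' sum of the log cell probabilities of the observed (decision, confidence)
#' responses in their (interval, contrast) conditions.
#'
#' @param dataset A trial tibble with columns `interval`, `contrast`,
#'   `decision`, `confidence`.
#' @param table A [response_cell_table()] result covering every condition in
#'   the dataset.
#' @return The scalar log-likelihood (0 for an empty dataset; `-Inf` if an
#'   observed cell has probability zero).
#' @export
dataset_loglik <- function(dataset, table) {
  if (nrow(dataset) == 0L) return(0)
  joined <- dplyr::left_join(
    as_tibble(dataset)[c("interval", "contrast", "decision", "confidence")],
    as_tibble(table),
    by = c("interval", "contrast", "decision", "confidence")
  )
  if (anyNA(joined$prob)) {
    abort("dataset contains a condition absent from the cell table",
          class = "confbms_error_invalid_input")
  }
  sum(log(joined$prob))
}

# per-condition x per-cell counts of a dataset, in kernel order
dataset_counts <- function(dataset, contrasts) {
  ncond <- 2L * length(contrasts)
  counts <- numeric(ncond * 12L)
  if (nrow(dataset) == 0L) return(counts)
  ci <- condition_index(dataset$interval, dataset$contrast, contrasts)
  idx <- (ci - 1L) * 12L + (dataset$decision - 1L) * 6L + dataset$confidence
  tab <- tabulate(idx, nbins = ncond * 12L)
  as.numeric(tab)
}

# shared standard-normal pool + condition layout for the likelihood kernel
make_kernel_pool <- function(contrasts, n_per_condition, seed, ...) {
  grid <- condition_grid(contrasts)
  ncond <- nrow(grid)
  N <- ncond * n_per_condition
  cond <- rep(seq_len(ncond) - 1L, each = n_per_condition)
  mu1 <- rep(ifelse(grid$interval == 1L, grid$contrast, 0), each = n_per_condition)
  mu2 <- rep(ifelse(grid$interval == 2L, grid$contrast, 0), each = n_per_condition)
  e <- with_substream(seed, ..., code = list(e1 = rnorm(N), e2 = rnorm(N)))
  list(e1 = e$e1, e2 = e$e2, mu1 = mu1, mu2 = mu2, cond = cond, ncond = ncond)
}

new_evidence_estimate <- function(method, model, per_run, n_is_samples,
                                  n_per_condition, seed) {
  kept <- per_run[per_run$kept, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("all evidence runs degenerate: no finite importance weights",
          class = "confbms_error_estimation_failure")
  }
  se <- if (nrow(kept) > 1L) {
    sd(kept$log_evidence) / sqrt(nrow(kept))
  } else {
    kept$se_within[1L]
  }
  # pool the kept runs for the point estimate (equivalent to one long run,
  # so the log-mean-exp small-sample bias shrinks with the total sample
  # count); the run-to-run spread supplies the standard error
  structure(list(log_evidence = log_sum_exp(kept$log_evidence) - log(nrow(kept)),
                 std_error = se,
                 per_run = per_run,
                 per_run_values = kept$log_evidence,
                 sigma_posterior_mean = mean(kept$sigma_mean),
                 n_is_samples = as.integer(n_is_samples),
                 n_runs = nrow(per_run),
                 n_per_condition = as.integer(n_per_condition),
                 method = method, model = model, seed = seed),
            class = "evidence_estimate")
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("<evidence_estimate: %s model, %s estimator>\n", x$model, x$method))
  cat(sprintf("  log evidence %.3f (SE %.3f) over %d run(s) of %d samples\n",
              x$log_evidence, x$std_error, x$n_runs, x$n_is_samples))
  invisible(x)
}

# one run of either estimator: p drawn from `draw_p` (prior or proposal),
# log-weights = loglik + log-density ratio
evidence_run <- function(dataset, model, prior, n_samples, n_per_condition,
                         run_seed, contrasts, min_branch, proposal_alpha) {
  draws <- draw_prior_components(n_samples, prior,
                                 seed = substream_seed(run_seed, "params"))
  conc <- flatten_cells(prior$dirichlet_concentration)
  if (!is.null(proposal_alpha)) {
    # importance proposal over p only; sigma and lapse stay on their priors
    pmat <- with_substream(run_seed, "proposal", code = {
      g <- matrix(rgamma(n_samples * 12L, shape = rep(proposal_alpha, each = n_samples)),
                  nrow = n_samples)
      g / rowSums(g)
    })
    norm_const <- (lgamma(sum(conc)) - sum(lgamma(conc))) -
      (lgamma(sum(proposal_alpha)) - sum(lgamma(proposal_alpha)))
    log_ratio <- as.vector(log(pmat) %*% (conc - proposal_alpha)) + norm_const
  } else {
    pmat <- draws$pmat
    log_ratio <- numeric(n_samples)
  }
  pool <- make_kernel_pool(contrasts, n_per_condition, run_seed, "pool")
  ll <- cpp_loglik_draws(pool$e1, pool$e2, pool$mu1, pool$mu2, pool$cond,
                         pool$ncond, model_code(model),
                         draws$sigma, draws$lapse, pmat,
                         sort(contrasts), dataset_counts(dataset, sort(contrasts)),
                         as.integer(n_per_condition), as.integer(min_branch))
  logw <- ll + log_ratio
  lse <- log_sum_exp(logw)
  if (lse == -Inf) {
    return(tibble(log_evidence = -Inf, se_within = NA_real_,
                  sigma_mean = NA_real_, n_degenerate = sum(is.infinite(ll)),
                  kept = FALSE))
  }
  w <- exp(logw - max(logw))
  se_within <- sd(w) / (sqrt(n_samples) * mean(w))  # delta-method SE of log mean
  wn <- w / sum(w)
  tibble(log_evidence = lse - log(n_samples),
         se_within = se_within,
         sigma_mean = sum(wn * draws$sigma),
         n_degenerate = sum(is.infinite(ll)),
         kept = TRUE)
}

#' Brute-force Monte-Carlo model evidence (prior sampling)
#'
#' Estimates the per-subject model evidence as the average likelihood over
#' draws from the prior, computed in log space. This estimator is unbiased
#' but high-variance (the likelihood is sharply peaked in parameter space);
#' it serves as the oracle against which the importance sampler is checked.
#'
#' @param dataset A trial tibble (columns `interval`, `contrast`,
#'   `decision`, `confidence`).
#' @param model `"difference"`, `"max"` or `"bayes"`.
#' @param prior A [prior_spec()].
#' @param n_prior_draws Prior draws per run.
#' @param n_per_condition Monte-Carlo cell-table samples per condition for
#'   each draw.
#' @param n_runs Number of independent repetitions (the run-to-run spread
#'   gives the standard error when `n_runs > 1`).
#' @param seed Optional integer root seed.
#' @param contrasts Contrast set of the design.
#' @param min_branch Minimum calibration samples per decision branch; draws
#'   violating it contribute zero likelihood.
#' @return An `evidence_estimate` object (natural-log evidence, standard
#'   error, per-run values).
#' @export
naive_evidence <- function(dataset, model, prior = prior_spec(),
                           n_prior_draws = 10000, n_per_condition = 1000,
                           n_runs = 1, seed = NULL,
                           contrasts = default_contrasts(), min_branch = 100) {
  check_model(model)
  if (n_prior_draws < 1 || n_runs < 1) {
    abort("`n_prior_draws` and `n_runs` must be at least 1",
          class = "confbms_error_invalid_parameter")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  runs <- purrr::map(seq_len(n_runs), function(r) {
    evidence_run(dataset, model, prior, n_prior_draws, n_per_condition,
                 substream_seed(seed, "naive", model, r), contrasts,
                 min_branch, proposal_alpha = NULL)
  })
  per_run <- dplyr::bind_rows(runs, .id = "run")
  new_evidence_estimate("naive", model, per_run, n_prior_draws,
                        n_per_condition, seed)
}

#' Model evidence by importance sampling with a counts-based proposal
#'
#' Estimates the per-subject model evidence with importance sampling: the
#' response probabilities `p` are drawn not from their flat Dirichlet prior
#' but from the proposal `Dirichlet(alpha + n)`, where `n` counts the
#' subject's (decision, confidence) responses irrespective of trial type —
#' an approximation to the posterior over `p`. Each draw is weighted by the
#' likelihood times the prior-to-proposal density ratio; `sigma` and the
#' lapse rate are always drawn from their priors. The algorithm is repeated
#' `n_runs` times with independent draws and sample pools; the estimate is
#' the mean of per-run log evidences with the across-run standard error.
#'
#' When the dataset is empty the proposal equals the prior, every weight is
#' one, and the log evidence is exactly zero.
#'
#' @inheritParams naive_evidence
#' @param n_is_samples Importance samples per run (default 1000).
#' @param n_runs Number of independent runs (default 10).
#' @return An `evidence_estimate`; `sigma_posterior_mean` holds the
#'   importance-weighted posterior mean of `sigma`.
#' @export
#' @examples
#' \donttest{
#' dat <- simulate_subject("difference", default_subject_params("figure8"),
#'                         design_trials(experiment_design(n_trials = 48), seed = 1),
#'                         n_calibration = 2000, seed = 1)
#' importance_evidence(dat, "difference", n_is_samples = 200, n_runs = 2,
#'                     n_per_condition = 500, seed = 1)
#' }
importance_evidence <- function(dataset, model, prior = prior_spec(),
                                n_is_samples = 1000, n_runs = 10,
                                n_per_condition = 12500, seed = NULL,
                                contrasts = default_contrasts(),
                                min_branch = 100) {
  check_model(model)
  if (n_is_samples < 1 || n_runs < 1) {
    abort("`n_is_samples` and `n_runs` must be at least 1",
          class = "confbms_error_invalid_parameter")
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  alpha_q <- flatten_cells(prior$dirichlet_concentration) +
    flatten_cells(count_matrix(dataset))
  runs <- purrr::map(seq_len(n_runs), function(r) {
    evidence_run(dataset, model, prior, n_is_samples, n_per_condition,
                 substream_seed(seed, "is", model, r), contrasts,
                 min_branch, proposal_alpha = alpha_q)
  })
  per_run <- dplyr::bind_rows(runs, .id = "run")
  if (any(!per_run$kept)) {
    warn(sprintf("%d of %d evidence runs degenerate; excluded from the estimate",
                 sum(!per_run$kept), n_runs))
  }
  new_evidence_estimate("importance", model, per_run, n_is_samples,
                        n_per_condition, seed)
}

#' Per-subject, per-model evidence table
#'
#' Runs the importance-sampling evidence estimator for every subject and
#' candidate model, returning a tidy table ready for [fixed_effects_posterior()]
#' and [random_effects_bms()].
#'
#' @param datasets Named list of trial tibbles, one per subject.
#' @param models Character vector of model names to compare.
#' @inheritParams importance_evidence
#' @return A tibble with columns `subject`, `model`, `log_evidence`,
#'   `std_error`, `sigma_posterior_mean`.
#' @export
evidence_table <- function(datasets, models = c("difference", "max", "bayes"),
                           prior = prior_spec(), n_is_samples = 1000,
                           n_runs = 10, n_per_condition = 12500, seed = NULL,
                           contrasts = default_contrasts(), min_branch = 100) {
  if (length(models) == 0L) {
    abort("`models` must be nonempty", class = "confbms_error_invalid_parameter")
  }
  if (is.null(names(datasets))) {
    names(datasets) <- sprintf("subject%02d", seq_along(datasets))
  }
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  purrr::map_dfr(names(datasets), function(subj) {
    purrr::map_dfr(models, function(m) {
      est <- importance_evidence(datasets[[subj]], m, prior, n_is_samples,
                                 n_runs, n_per_condition,
                                 seed = substream_seed(seed, "subject", subj),
                                 contrasts = contrasts, min_branch = min_branch)
      tibble(subject = subj, model = m,
             log_evidence = est$log_evidence, std_error = est$std_error,
             sigma_posterior_mean = est$sigma_posterior_mean)
    })
  })
}
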