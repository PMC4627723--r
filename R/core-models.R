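#' Draw sensory signals for stimulus conditions
#'
#' On each trial the observer receives a pair of noisy sensory signals
#' `(x1, x2)`, one per viewing interval. The signal from the target interval
#' is Gaussian with mean equal to the added contrast `s` and variance
#' `sigma^2 / 2`; the signal from the other interval has mean 0 and the same
#' variance, so the difference `x2 - x1` has variance `sigma^2`.
#'
#' @param conditions A data frame with columns `interval` (1 or 2) and
#'   `contrast` (positive added contrast), one row per trial type.
#' @param sigma Sensory noise standard deviation, in contrast units.
#' @param n Number of independent draws per row of `conditions`.
#' @param seed Optional integer seed; draws are reproducible given the seed.
#' @return A tibble with columns `interval`, `contrast`, `x1`, `x2`; each
#'   input row appears `n` times.
#' @export
#' @examples
#' sample_sensory(tibble::tibble(interval = 1, contrast = 0.07),
#'                sigma = 0.07, n = 5, seed = 1)
sample_sensory <- function(conditions, sigma, n = 1, seed = NULL) {
  check_sigma(sigma)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a positive integer",
          class = "confbms_error_invalid_parameter")
  }
  stopifnot(is.data.frame(conditions),
            all(c("interval", "contrast") %in% names(conditions)))
  idx <- rep(seq_len(nrow(conditions)), each = as.integer(n))
  out <- tibble(interval = as.integer(conditions$interval[idx]),
                contrast = conditions$contrast[idx])
  if (!all(out$interval %in% c(1L, 2L))) {
    abort("`interval` must be 1 or 2", class = "confbms_error_invalid_parameter")
  }
  m1 <- ifelse(out$interval == 1L, out$contrast, 0)
  m2 <- ifelse(out$interval == 2L, out$contrast, 0)
  sdv <- sigma / sqrt(2)
  nn <- nrow(out)
  xs <- with_substream(seed, "sensory", code = {
    list(x1 = m1 + sdv * rnorm(nn), x2 = m2 + sdv * rnorm(nn))
  })
  out$x1 <- xs$x1
  out$x2 <- xs$x2
  out
}

#' Posterior probability of each target interval given the sensory signals
#'
#' The ideal observer's posterior over the target interval, marginalizing the
#' unknown added contrast over the contrast set with equal weights, and using
#' equal prior probability for the two intervals. Computed in log space with
#' a max shift, so it is accurate for arbitrarily large `|x| / sigma`.
#'
#' @param x1,x2 Numeric vectors of sensory signals (recycled to a common
#'   length).
#' @param sigma Sensory noise standard deviation.
#' @param contrasts Contrast set marginalized over (default
#'   [default_contrasts()]).
#' @return A tibble with columns `p1` and `p2` (`P(i = 1 | x)` and
#'   `P(i = 2 | x)`); the two columns sum to one.
#' @export
#' @examples
#' bayes_posterior(0, 0.07, sigma = 0.07)
bayes_posterior <- function(x1, x2, sigma, contrasts = default_contrasts()) {
  check_sigma(sigma)
  check_contrast_set(contrasts)
  n <- max(length(x1), length(x2))
  x1 <- rep_len(x1, n)
  x2 <- rep_len(x2, n)
  sdv <- sigma / sqrt(2)
  # log P(x | s, i): target component centred on s, the other on 0
  l1 <- vapply(contrasts,
               function(s) dnorm(x1, s, sdv, log = TRUE) + dnorm(x2, 0, sdv, log = TRUE),
               numeric(n))
  l2 <- vapply(contrasts,
               function(s) dnorm(x1, 0, sdv, log = TRUE) + dnorm(x2, s, sdv, log = TRUE),
               numeric(n))
  l1 <- matrix(l1, nrow = n)
  l2 <- matrix(l2, nrow = n)
  m <- pmax(apply(l1, 1L, max), apply(l2, 1L, max))
  a <- rowSums(exp(l1 - m))
  b <- rowSums(exp(l2 - m))
  tibble(p1 = a / (a + b), p2 = b / (a + b))
}

#' Decision variable of a confidence model
#'
#' The scalar internal variable compared against a single threshold to choose
#' the interval. The Difference and Max models both use the signal difference
#' `x2 - x1`; the Bayes-optimal model uses the posterior probability that the
#' target was in interval 2.
#'
#' @inheritParams bayes_posterior
#' @param model One of `"difference"`, `"max"`, `"bayes"`.
#' @return A numeric vector of decision-variable values.
#' @export
decision_variable <- function(x1, x2, model, sigma = NULL,
                              contrasts = default_contrasts()) {
  check_model(model)
  if (model == "bayes") {
    bayes_posterior(x1, x2, sigma, contrasts)$p2
  } else {
    x2 - x1
  }
}

#' Confidence variable of a confidence model, given the decision
#'
#' The scalar internal evidence for the chosen interval, compared against the
#' ordered confidence thresholds. Difference model: signed signal difference
#' in favour of the choice. Max model: the signal from the chosen interval
#' only. Bayes model: the posterior probability that the choice is correct.
#'
#' @inheritParams decision_variable
#' @param decision Integer vector of decisions (1 or 2).
#' @return A numeric vector of confidence-variable values.
#' @export
confidence_variable <- function(x1, x2, decision, model, sigma = NULL,
                                contrasts = default_contrasts()) {
  check_model(model)
  decision <- check_decision(decision)
  switch(model,
    difference = ifelse(decision == 1L, x1 - x2, x2 - x1),
    max = ifelse(decision == 1L, rep_len(x1, length(decision)),
                 rep_len(x2, length(decision))),
    bayes = {
      post <- bayes_posterior(x1, x2, sigma, contrasts)
      ifelse(decision == 1L, post$p1, post$p2)
    }
  )
}

#' Apply the decision rule
#'
#' Interval 2 is chosen when the decision variable strictly exceeds the
#' decision threshold; interval 1 otherwise (including exact equality).
#'
#' @param z_d Numeric vector of decision-variable values.
#' @param threshold Scalar decision threshold (may be infinite).
#' @return Integer vector of decisions (1 or 2).
#' @export
apply_decision_rule <- function(z_d, threshold) {
  stopifnot(length(threshold) == 1L, !is.na(threshold))
  ifelse(z_d > threshold, 2L, 1L)
}

#' Apply the confidence rule
#'
#' Maps the confidence variable to a report `c` in 1..6 such that
#' `theta[d, c - 1] < z_c <= theta[d, c]`, with the outer thresholds fixed at
#' minus and plus infinity so every value is covered. Values exactly equal to
#' a threshold fall in the lower bin.
#'
#' @param z_c Numeric vector of confidence-variable values.
#' @param decision Integer vector of decisions (1 or 2), same length.
#' @param thresholds A [threshold_set()] or a 2 x 7 confidence-threshold
#'   matrix (columns 1 and 7 at -Inf / +Inf, rows nondecreasing).
#' @return Integer vector of confidence levels in 1..6.
#' @export
apply_confidence_rule <- function(z_c, decision, thresholds) {
  conf <- if (inherits(thresholds, "threshold_set")) thresholds$confidence else thresholds
  check_confidence_matrix(conf)
  decision <- check_decision(decision)
  out <- integer(length(z_c))
  for (d in 1:2) {
    idx <- decision == d
    if (any(idx)) {
      out[idx] <- findInterval(z_c[idx], conf[d, 2:6], left.open = TRUE) + 1L
    }
  }
  out
}

#' Mix a response-cell distribution with uniform lapses
#'
#' With probability `lapse` the subject responds at random, uniformly over
#' the 12 (decision, confidence) cells; the observed cell distribution is the
#' corresponding mixture. Handling lapses analytically (rather than by
#' simulating lapse trials) keeps every cell probability at least
#' `lapse / 12`, so log-likelihoods stay finite whenever `lapse > 0`.
#'
#' @param cell_probs A nonnegative 2 x 6 matrix summing to 1.
#' @param lapse Lapse probability in `[0, 1]`.
#' @return The mixed 2 x 6 matrix `(1 - lapse) * cell_probs + lapse / 12`.
#' @export
lapse_mix <- function(cell_probs, lapse) {
  if (!is.numeric(lapse) || length(lapse) != 1L || is.na(lapse) ||
      lapse < 0 || lapse > 1) {
    abort("`lapse` must be a single value in [0, 1]",
          class = "confbms_error_invalid_parameter")
  }
  stopifnot(is.matrix(cell_probs), all(dim(cell_probs) == c(2L, 6L)))
  if (any(cell_probs < 0) || abs(sum(cell_probs) - 1) > 1e-8) {
    abort("`cell_probs` must be nonnegative and sum to 1",
          class = "confbms_error_invalid_parameter")
  }
  (1 - lapse) * cell_probs + lapse / 12
}

#' Decision and confidence thresholds of one subject
#'
#' @param decision Scalar decision threshold.
#' @param confidence 2 x 7 matrix of confidence thresholds; column 1 must be
#'   `-Inf`, column 7 `+Inf`, and each row nondecreasing.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(decision, confidence) {
  stopifnot(is.numeric(decision), length(decision) == 1L, !is.na(decision))
  check_confidence_matrix(confidence)
  structure(list(decision = decision, confidence = confidence),
            class = "threshold_set")
}

check_confidence_matrix <- function(conf) {
  if (!is.matrix(conf) || !all(dim(conf) == c(2L, 7L)) ||
      any(conf[, 1L] != -Inf) || any(conf[, 7L] != Inf) ||
      any(apply(conf, 1L, is.unsorted))) {
    abort("confidence thresholds must be a 2 x 7 matrix with -Inf / +Inf ends and nondecreasing rows",
          class = "confbms_error_invalid_parameter")
  }
  invisible(conf)
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set>\n")
  cat("  decision threshold:", format(x$decision, digits = 4), "\n")
  cat("  confidence thresholds (interior):\n")
  print(round(x$confidence[, 2:6, drop = FALSE], 4))
  invisible(x)
}

#' Subject parameters: sensory noise, lapse rate and response probabilities
#'
#' The full parameter set of one subject: the sensory noise `sigma`, the
#' lapse rate, and the 2 x 6 marginal response-probability matrix `p` whose
#' entry `p[d, c]` is the probability (aggregated over trial types) of
#' decision `d` with confidence `c`. The response probabilities are a
#' one-to-one reparametrization of the decision and confidence thresholds,
#' which makes a flat Dirichlet a natural prior.
#'
#' @param sigma Positive sensory noise standard deviation (contrast units).
#' @param lapse Lapse probability in `[0, 1]`.
#' @param response_probs Nonnegative 2 x 6 matrix summing to 1.
#' @return An object of class `subject_params`.
#' @export
#' @examples
#' subject_params(0.07, 0, matrix(1 / 12, 2, 6))
subject_params <- function(sigma, lapse, response_probs) {
  check_sigma(sigma)
  if (!is.numeric(lapse) || length(lapse) != 1L || is.na(lapse) ||
      lapse < 0 || lapse > 1) {
    abort("`lapse` must be in [0, 1]", class = "confbms_error_invalid_parameter")
  }
  stopifnot(is.matrix(response_probs), all(dim(response_probs) == c(2L, 6L)))
  if (any(response_probs < 0) || abs(sum(response_probs) - 1) > 1e-8) {
    abort("`response_probs` must be nonnegative and sum to 1",
          class = "confbms_error_invalid_parameter")
  }
  structure(list(sigma = sigma, lapse = lapse,
                 response_probs = unflatten_cells(flatten_cells(response_probs))),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat("<subject_params> sigma =", format(x$sigma, digits = 4),
      " lapse =", format(x$lapse, digits = 4), "\n")
  print(round(x$response_probs, 4))
  invisible(x)
}
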