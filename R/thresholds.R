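#' Build a pooled sample of decision variables across all conditions
#'
#' Draws `n_per_condition` sensory samples from each of the eight
#' (interval, contrast) conditions in equal proportion, matching the balanced
#' experimental design, and computes the model's decision variable for each
#' draw. The pool represents the marginal distribution of the decision
#' variable used to convert response probabilities into thresholds;
#' confidence variables are computed later, once decisions are assigned by a
#' calibrated decision threshold.
#'
#' @inheritParams decision_variable
#' @param n_per_condition Number of draws per condition (pool size is eight
#'   times this).
#' @param seed Optional integer seed.
#' @return A tibble with columns `interval`, `contrast`, `x1`, `x2`, `z_d`,
#'   carrying attributes `model`, `sigma` and `contrasts`.
#' @export
build_sample_pool <- function(model, sigma, contrasts = default_contrasts(),
                              n_per_condition = 12500, seed = NULL) {
  check_model(model)
  check_sigma(sigma)
  pool <- sample_sensory(condition_grid(contrasts), sigma,
                         n = n_per_condition, seed = seed)
  pool$z_d <- decision_variable(pool$x1, pool$x2, model, sigma, contrasts)
  attr(pool, "model") <- model
  attr(pool, "sigma") <- sigma
  attr(pool, "contrasts") <- sort(contrasts)
  attr(pool, "n_per_condition") <- as.integer(n_per_condition)
  pool
}

#' Decision threshold matching a target choice probability
#'
#' Inverts the empirical distribution of decision-variable samples: returns
#' the threshold below which a fraction `p_d1` of samples lie (the modelled
#' probability of choosing interval 1), placed midway between the two order
#' statistics that straddle the target count. Boundary targets put the
#' threshold strictly below the minimum or above the maximum sample.
#'
#' @param z_d Numeric vector of decision-variable samples.
#' @param p_d1 Target probability of decision 1, in `[0, 1]`.
#' @return The scalar decision threshold.
#' @export
decision_threshold_from_prob <- function(z_d, p_d1) {
  if (length(z_d) == 0L) {
    abort("empty decision-variable sample set",
          class = "confbms_error_invalid_state")
  }
  if (!is.numeric(p_d1) || length(p_d1) != 1L || is.na(p_d1) ||
      p_d1 < 0 || p_d1 > 1) {
    abort("`p_d1` must be in [0, 1]", class = "confbms_error_invalid_parameter")
  }
  n <- length(z_d)
  zs <- sort(z_d)
  k <- min(max(round_half_up(p_d1 * n), 0), n)
  if (k == 0) zs[1L] - 1 else if (k == n) zs[n] + 1 else (zs[k] + zs[k + 1L]) / 2
}

#' Confidence thresholds matching a conditional report distribution
#'
#' For each decision branch, places the five interior confidence thresholds
#' between order statistics of the branch's confidence-variable samples so
#' that the empirical mass in each bin equals the target conditional
#' distribution `P(c | d)` up to sample granularity. Cumulative counts are
#' rounded (half up) so the six bin counts sum exactly to the branch size.
#'
#' @param z_c_by_decision List of two numeric vectors: confidence-variable
#'   samples for decisions 1 and 2 (samples from the other branch already
#'   discarded).
#' @param p_c_given_d 2 x 6 matrix of conditional probabilities; each row
#'   sums to 1.
#' @param min_branch Minimum samples required per branch (default 100);
#'   fewer raises a degenerate-branch error.
#' @return A 2 x 7 confidence-threshold matrix.
#' @export
confidence_thresholds_from_probs <- function(z_c_by_decision, p_c_given_d,
                                             min_branch = 100) {
  stopifnot(is.list(z_c_by_decision), length(z_c_by_decision) == 2L,
            is.matrix(p_c_given_d), all(dim(p_c_given_d) == c(2L, 6L)))
  if (any(p_c_given_d < 0) || any(abs(rowSums(p_c_given_d) - 1) > 1e-8)) {
    abort("each row of `p_c_given_d` must be a probability distribution",
          class = "confbms_error_invalid_parameter")
  }
  conf <- matrix(NA_real_, 2L, 7L)
  conf[, 1L] <- -Inf
  conf[, 7L] <- Inf
  for (d in 1:2) {
    conf[d, 2:6] <- branch_thresholds(z_c_by_decision[[d]], p_c_given_d[d, ],
                                      min_branch)
  }
  check_confidence_matrix(conf)
  conf
}

# interior thresholds of one decision branch (order-statistic placement)
branch_thresholds <- function(z_c, p_row, min_branch) {
  nd <- length(z_c)
  if (nd < min_branch) {
    abort(sprintf("decision branch has %d samples (< %d): cannot calibrate confidence thresholds",
                  nd, min_branch),
          class = "confbms_error_degenerate_branch")
  }
  zs <- sort(z_c)
  ks <- round_half_up(cumsum(p_row)[1:5] * nd)
  ks <- pmin(pmax(cummax(ks), 0), nd)
  thr <- numeric(5L)
  for (j in 1:5) {
    k <- ks[j]
    thr[j] <- if (k == 0) zs[1L] - 1 else if (k == nd) zs[nd] + 1 else (zs[k] + zs[k + 1L]) / 2
  }
  thr
}

#' Calibrate a full threshold set from response probabilities
#'
#' Implements the threshold reparametrization on a sample pool: the decision
#' threshold is set from the marginal probability of decision 1, decisions
#' are assigned to every pool sample, confidence variables are computed given
#' those decisions, and per-branch confidence thresholds are set from the
#' conditional report distribution. A branch that receives a positive target
#' count smaller than `min_branch` raises a degenerate-branch error; a
#' branch with zero target mass is left unreachable.
#'
#' @param pool A sample pool from [build_sample_pool()].
#' @param response_probs 2 x 6 joint response-probability matrix (sums to 1).
#' @inheritParams confidence_thresholds_from_probs
#' @return A [threshold_set()].
#' @export
calibrate_thresholds <- function(pool, response_probs, min_branch = 100) {
  stopifnot(is.data.frame(pool), all(c("x1", "x2", "z_d") %in% names(pool)))
  model <- attr(pool, "model")
  sigma <- attr(pool, "sigma")
  contrasts <- attr(pool, "contrasts")
  if (any(response_probs < 0) || abs(sum(response_probs) - 1) > 1e-8) {
    abort("`response_probs` must be nonnegative and sum to 1",
          class = "confbms_error_invalid_parameter")
  }
  p_d1 <- sum(response_probs[1L, ])
  theta_d <- decision_threshold_from_prob(pool$z_d, p_d1)
  d <- apply_decision_rule(pool$z_d, theta_d)
  z_c <- confidence_variable(pool$x1, pool$x2, d, model, sigma, contrasts)
  conf <- matrix(NA_real_, 2L, 7L)
  conf[, 1L] <- -Inf
  conf[, 7L] <- Inf
  for (d0 in 1:2) {
    idx <- d == d0
    nd <- sum(idx)
    pd <- sum(response_probs[d0, ])
    if (nd == 0L) {
      # zero (or sub-resolution) target mass: branch never occurs in the
      # pool; mark it unreachable rather than inventing thresholds
      conf[d0, 2:6] <- Inf
    } else {
      conf[d0, 2:6] <- branch_thresholds(z_c[idx], response_probs[d0, ] / pd,
                                         min_branch)
    }
  }
  threshold_set(theta_d, conf)
}

#' Assign decisions and confidence reports to sensory samples
#'
#' Applies a calibrated threshold set to raw sensory samples: computes the
#' model's decision variable, thresholds it, computes the confidence variable
#' given the decision, and bins it.
#'
#' @inheritParams decision_variable
#' @param thresholds A [threshold_set()].
#' @return A tibble with integer columns `decision` and `confidence`.
#' @export
assign_responses <- function(x1, x2, model, thresholds, sigma = NULL,
                             contrasts = default_contrasts()) {
  check_model(model)
  z_d <- decision_variable(x1, x2, model, sigma, contrasts)
  d <- apply_decision_rule(z_d, thresholds$decision)
  z_c <- confidence_variable(x1, x2, d, model, sigma, contrasts)
  tibble(decision = as.integer(d),
         confidence = apply_confidence_rule(z_c, d, thresholds))
}

#' Monte-Carlo response-cell probability table
#'
#' The forward map from subject parameters to the probability of every
#' (decision, confidence) response cell in every stimulus condition.
#' Thresholds are calibrated from the subject's marginal response
#' probabilities on a pooled sample (all conditions in equal proportion);
#' per-condition cell frequencies are then computed from the same draws, and
#' the lapse mixture is applied analytically.
#'
#' @inheritParams build_sample_pool
#' @param params A [subject_params()] object.
#' @inheritParams confidence_thresholds_from_probs
#' @return A tibble of class `cell_prob_table` with columns `interval`,
#'   `contrast`, `decision`, `confidence`, `prob` (96 rows; each condition's
#'   12 cells sum to 1).
#' @export
#' @examples
#' params <- default_subject_params("figure8")
#' tab <- response_cell_table("max", params, n_per_condition = 2000, seed = 1)
#' dplyr::summarise(dplyr::group_by(tab, interval, contrast), total = sum(prob))
response_cell_table <- function(model, params,
                                contrasts = default_contrasts(),
                                n_per_condition = 12500, seed = NULL,
                                min_branch = 100) {
  check_model(model)
  stopifnot(inherits(params, "subject_params"))
  pool <- build_sample_pool(model, params$sigma, contrasts,
                            n_per_condition, seed)
  thresholds <- calibrate_thresholds(pool, params$response_probs, min_branch)
  resp <- assign_responses(pool$x1, pool$x2, model, thresholds,
                           params$sigma, attr(pool, "contrasts"))
  counts <- dplyr::count(
    tibble(interval = pool$interval, contrast = pool$contrast,
           decision = resp$decision, confidence = resp$confidence),
    .data$interval, .data$contrast, .data$decision, .data$confidence
  )
  full <- tidyr::expand_grid(condition_grid(contrasts),
                             decision = 1:2, confidence = 1:6)
  tab <- dplyr::left_join(full, counts,
                          by = c("interval", "contrast", "decision", "confidence"))
  tab$n[is.na(tab$n)] <- 0L
  tab$prob <- (1 - params$lapse) * tab$n / n_per_condition + params$lapse / 12
  tab$n <- NULL
  structure(tab,
            class = c("cell_prob_table", class(tab)),
            model = model, sigma = params$sigma, lapse = params$lapse,
            contrasts = sort(contrasts),
            n_samples = as.integer(n_per_condition) * nrow(condition_grid(contrasts)),
            thresholds = thresholds)
}

#' Aggregate a cell table over conditions
#'
#' Averages the per-condition cell probabilities with equal weights (the
#' balanced design), giving the marginal response distribution implied by the
#' table; for a lapse-free table this reproduces the calibrating response
#' probabilities up to sample granularity.
#'
#' @param table A [response_cell_table()] result.
#' @return A 2 x 6 matrix of marginal cell probabilities.
#' @export
aggregate_cell_probs <- function(table) {
  agg <- dplyr::summarise(
    dplyr::group_by(as_tibble(table), .data$decision, .data$confidence),
    prob = mean(.data$prob), .groups = "drop"
  )
  m <- matrix(0, 2L, 6L)
  m[cbind(agg$decision, agg$confidence)] <- agg$prob
  unflatten_cells(flatten_cells(m))
}
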