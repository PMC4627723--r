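# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (direct density products instead of
# log-space, closed forms, numeric integration) so that agreement is a real
# cross-check.

# Target-interval posterior by direct evaluation of the eight Gaussian
# likelihood products (no log-space tricks).
oracle_bayes_posterior <- function(x1, x2, sigma, contrasts = default_contrasts()) {
  sdv <- sigma / sqrt(2)
  lik <- function(i) {
    sum(vapply(contrasts, function(s) {
      m1 <- if (i == 1) s else 0
      m2 <- if (i == 2) s else 0
      dnorm(x1, m1, sdv) * dnorm(x2, m2, sdv)
    }, numeric(1)))
  }
  a <- lik(1)
  b <- lik(2)
  c(p1 = a / (a + b), p2 = b / (a + b))
}

# Textbook one-sample t statistic.
oracle_tstat <- function(x) mean(x) / (sd(x) / sqrt(length(x)))

# Mixture CDF of the difference-model decision variable z = x2 - x1 pooled
# over the eight balanced conditions: means -s (i = 1) and +s (i = 2),
# common sd sigma.
oracle_diff_mix_cdf <- function(t, sigma, contrasts = default_contrasts()) {
  mus <- c(-contrasts, contrasts)
  mean(pnorm(t, mean = mus, sd = sigma))
}

oracle_diff_mix_quantile <- function(p, sigma, contrasts = default_contrasts()) {
  stats::uniroot(function(t) oracle_diff_mix_cdf(t, sigma, contrasts) - p,
                 interval = c(-10, 10), tol = 1e-12)$root
}

# Analytic per-condition cell probabilities for the difference model with
# b = 0: thresholds from the pooled mixture quantiles, cell mass from the
# per-condition normal CDF between thresholds (z^C for d = 1 is -z^D, so
# the d = 1 bins are reflected).
oracle_diff_cell_table <- function(p, sigma, contrasts = default_contrasts()) {
  p_d1 <- sum(p[1, ])
  theta_d <- oracle_diff_mix_quantile(p_d1, sigma, contrasts)
  f_theta <- oracle_diff_mix_cdf(theta_d, sigma, contrasts)
  # conditional quantiles of z^D within each branch
  q_in_branch <- function(mass_below, d) {
    # mass_below: conditional cumulative mass within branch d
    target <- if (d == 2) f_theta + mass_below * (1 - f_theta)
              else f_theta * (1 - mass_below)  # d=1: z^C = -z^D reverses order
    oracle_diff_mix_quantile(target, sigma, contrasts)
  }
  grid <- condition_grid(contrasts)
  out <- array(0, dim = c(nrow(grid), 2, 6))
  for (d in 1:2) {
    pc <- p[d, ] / sum(p[d, ])
    cum <- c(0, cumsum(pc))
    cuts <- vapply(cum, q_in_branch, numeric(1), d = d)  # z^D scale
    for (g in seq_len(nrow(grid))) {
      mu <- if (grid$interval[g] == 1) -grid$contrast[g] else grid$contrast[g]
      for (cc in 1:6) {
        lo <- min(cuts[cc], cuts[cc + 1]); hi <- max(cuts[cc], cuts[cc + 1])
        out[g, d, cc] <- pnorm(hi, mu, sigma) - pnorm(lo, mu, sigma)
      }
    }
  }
  out
}

uniform_params <- function(sigma = 0.07, lapse = 0) {
  subject_params(sigma, lapse, matrix(1 / 12, 2, 6))
}

random_response_probs <- function() {
  g <- matrix(rgamma(12, shape = 1), 2, 6)
  g / sum(g)
}

# A sample pool built from explicit standard-normal deviates, bit-identical
# to the layout the C++ kernel receives.
manual_pool <- function(model, sigma, e1, e2, n_per_condition,
                        contrasts = default_contrasts(), shift = 0) {
  grid <- condition_grid(contrasts)
  cond <- rep(seq_len(nrow(grid)), each = n_per_condition)
  mu1 <- ifelse(grid$interval == 1, grid$contrast, 0)[cond]
  mu2 <- ifelse(grid$interval == 2, grid$contrast, 0)[cond]
  sdv <- sigma / sqrt(2)
  pool <- tibble::tibble(interval = grid$interval[cond],
                         contrast = grid$contrast[cond],
                         x1 = mu1 + sdv * e1 + shift,
                         x2 = mu2 + sdv * e2 + shift)
  pool$z_d <- decision_variable(pool$x1, pool$x2, model, sigma, contrasts)
  attr(pool, "model") <- model
  attr(pool, "sigma") <- sigma
  attr(pool, "contrasts") <- sort(contrasts)
  attr(pool, "n_per_condition") <- n_per_condition
  pool
}

# cell table (condition x 96 vector layout) from the R calibration path on a
# manual pool
r_path_cell_probs <- function(pool, p, lapse = 0, min_branch = 100) {
  thr <- calibrate_thresholds(pool, p, min_branch)
  resp <- assign_responses(pool$x1, pool$x2, attr(pool, "model"), thr,
                           attr(pool, "sigma"), attr(pool, "contrasts"))
  npc <- attr(pool, "n_per_condition")
  ci <- match(paste(pool$interval, pool$contrast),
              paste(condition_grid(attr(pool, "contrasts"))$interval,
                    condition_grid(attr(pool, "contrasts"))$contrast))
  idx <- (ci - 1L) * 12L + (resp$decision - 1L) * 6L + resp$confidence
  (1 - lapse) * tabulate(idx, nbins = 8L * 12L) / npc + lapse / 12
}

with_seed_sample <- function(x, seed) withr::with_seed(seed, sample(x))
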