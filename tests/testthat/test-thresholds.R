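test_that("sample pools have the right size, range and determinism", {
  pool <- build_sample_pool("bayes", 0.07, n_per_condition = 200, seed = 21)
  expect_equal(nrow(pool), 8 * 200)
  expect_true(all(pool$z_d > 0 & pool$z_d < 1))  # posterior-valued
  pool2 <- build_sample_pool("bayes", 0.07, n_per_condition = 200, seed = 21)
  expect_identical(pool, pool2)
  expect_equal(unname(table(paste(pool$interval, pool$contrast))),
               rep(200L, 8), ignore_attr = TRUE)
})

test_that("decision threshold inverts the empirical distribution", {
  set.seed(22)
  z <- rnorm(2e5)
  # Gaussian quantile oracle: p = pnorm(1) -> threshold ~ 1
  expect_lt(abs(decision_threshold_from_prob(z, pnorm(1)) - 1), 0.015)
  expect_lt(abs(decision_threshold_from_prob(z, 0.5) - 0), 0.01)
  # boundary targets fall outside the sample range
  expect_lt(decision_threshold_from_prob(z, 0), min(z))
  expect_gt(decision_threshold_from_prob(z, 1), max(z))
  # symmetric set: p = 1/2 lands at the centre
  zs <- c(-3, -1, 1, 3)
  expect_equal(decision_threshold_from_prob(zs, 0.5), 0)
  expect_error(decision_threshold_from_prob(numeric(0), 0.5),
               class = "confbms_error_invalid_state")
})

test_that("decision threshold is weakly monotone in the target probability", {
  set.seed(23)
  z <- rnorm(5000)
  ps <- sort(runif(50))
  th <- vapply(ps, function(p) decision_threshold_from_prob(z, p), numeric(1))
  expect_true(all(diff(th) >= 0))
})

test_that("confidence thresholds match conditional quantiles and round-trip", {
  set.seed(24)
  n <- 1e5
  z <- list(runif(n), runif(n))
  punif <- matrix(1 / 6, 2, 6)
  conf <- confidence_thresholds_from_probs(z, punif)
  expect_equal(conf[1, 2:6], (1:5) / 6, tolerance = 0.01)
  expect_equal(conf[2, 2:6], (1:5) / 6, tolerance = 0.01)

  # all mass on c = 6: every interior threshold below the smallest sample
  ptop <- rbind(c(0, 0, 0, 0, 0, 1), rep(1 / 6, 6))
  conf_top <- confidence_thresholds_from_probs(z, ptop)
  expect_true(all(conf_top[1, 2:6] <= min(z[[1]])))

  # round trip: re-binning the same samples reproduces the target masses
  for (rep in 1:5) {
    p <- random_response_probs()
    pc <- p / rowSums(p)
    conf_r <- confidence_thresholds_from_probs(z, pc)
    ts <- threshold_set(0, conf_r)
    for (d in 1:2) {
      cc <- apply_confidence_rule(z[[d]], rep(d, n), ts)
      freq <- tabulate(cc, 6) / n
      expect_lt(max(abs(freq - pc[d, ])), 2 / n)
    }
  }
  expect_error(confidence_thresholds_from_probs(list(runif(50), runif(n)), punif),
               class = "confbms_error_degenerate_branch")
})

test_that("calibration round-trips the full response matrix for all models", {
  npc <- 2000
  for (model in c("difference", "max", "bayes")) {
    pool <- build_sample_pool(model, 0.07, n_per_condition = npc, seed = 25)
    for (rep in 1:3) {
      set.seed(100 * rep)
      p <- random_response_probs()
      thr <- calibrate_thresholds(pool, p)
      resp <- assign_responses(pool$x1, pool$x2, model, thr, 0.07)
      agg <- matrix(0, 2, 6)
      for (d in 1:2) for (cc in 1:6) {
        agg[d, cc] <- mean(resp$decision == d & resp$confidence == cc)
      }
      expect_lt(max(abs(agg - p)), 2 / (8 * npc))
    }
  }
})

test_that("uniform targets give a uniform aggregated cell distribution", {
  npc <- 2500
  for (model in c("difference", "max", "bayes")) {
    tab <- response_cell_table(model, uniform_params(), n_per_condition = npc,
                               seed = 26)
    agg <- aggregate_cell_probs(tab)
    expect_lt(max(abs(agg - 1 / 12)), 2 / (8 * npc))
  }
})

test_that("cell tables are per-condition distributions with the lapse floor", {
  params <- subject_params(0.07, 0.2, matrix(1 / 12, 2, 6))
  tab <- response_cell_table("difference", params, n_per_condition = 1000, seed = 27)
  sums <- dplyr::summarise(dplyr::group_by(tab, interval, contrast),
                           s = sum(prob), .groups = "drop")
  expect_equal(sums$s, rep(1, 8), tolerance = 1e-12)
  expect_true(all(tab$prob >= 0.2 / 12))
  # pure lapse erases all structure
  tab1 <- response_cell_table("max", subject_params(0.07, 1, matrix(1 / 12, 2, 6)),
                              n_per_condition = 500, seed = 28)
  expect_equal(tab1$prob, rep(1 / 12, 96))
})

test_that("difference-model tables depend on the signals only through x2 - x1", {
  set.seed(29)
  npc <- 1000
  e1 <- rnorm(8 * npc); e2 <- rnorm(8 * npc)
  p <- random_response_probs()
  base <- r_path_cell_probs(manual_pool("difference", 0.07, e1, e2, npc), p)
  shifted <- r_path_cell_probs(manual_pool("difference", 0.07, e1, e2, npc,
                                           shift = 0.37), p)
  expect_equal(base, shifted, tolerance = 1e-12)
})

test_that("the C++ likelihood kernel reproduces the R calibration path exactly", {
  set.seed(30)
  npc <- 1200L
  e1 <- rnorm(8 * npc); e2 <- rnorm(8 * npc)
  grid <- condition_grid()
  cond0 <- rep(0:7, each = npc)
  mu1 <- rep(ifelse(grid$interval == 1, grid$contrast, 0), each = npc)
  mu2 <- rep(ifelse(grid$interval == 2, grid$contrast, 0), each = npc)
  for (model in c("difference", "max", "bayes")) {
    p <- random_response_probs()
    lapse <- 0.02
    pool <- manual_pool(model, 0.07, e1, e2, npc)
    r_tab <- r_path_cell_probs(pool, p, lapse = lapse)
    c_tab <- confbms:::cpp_cell_table(
      e1, e2, mu1, mu2, as.integer(cond0), 8L,
      match(model, c("difference", "max", "bayes")) - 1L,
      0.07, lapse, as.vector(t(p)), default_contrasts(), npc, 100L)
    expect_equal(r_tab, c_tab, tolerance = 1e-12)
  }
})

test_that("difference-model cell tables match the analytic mixture oracle", {
  set.seed(31)
  p <- random_response_probs()
  npc <- 12500
  tab <- response_cell_table("difference", subject_params(0.07, 0, p),
                             n_per_condition = npc, seed = 32)
  ora <- oracle_diff_cell_table(p, 0.07)
  grid <- condition_grid()
  worst <- 0
  for (g in seq_len(nrow(grid))) {
    sub <- tab[tab$interval == grid$interval[g] & tab$contrast == grid$contrast[g], ]
    for (r in seq_len(nrow(sub))) {
      q <- ora[g, sub$decision[r], sub$confidence[r]]
      se <- sqrt(q * (1 - q) / npc) + 2 / npc  # binomial + calibration granularity
      worst <- max(worst, abs(sub$prob[r] - q) / (se + 1e-12))
    }
  }
  # 96 cells compared; allow a generous multiple of the per-cell SE
  expect_lt(worst, 5)
})

test_that("max-model errors at s = 0.07 are bimodal in confidence", {
  tab <- response_cell_table("max", uniform_params(), n_per_condition = 12500,
                             seed = 33)
  err <- tab[tab$interval == 2 & tab$contrast == 0.07 & tab$decision == 1, ]
  p1 <- err$prob[err$confidence == 1]
  p3 <- err$prob[err$confidence == 3]
  expect_lt(p1, p3)  # a low-confidence error is rarer than a mid-confidence one
})

test_that("degenerate response targets raise a diagnosable error", {
  pool <- build_sample_pool("difference", 0.07, n_per_condition = 500, seed = 34)
  p <- matrix(c(0.004 / 6, 0.996 / 6), 2, 6)[c(1, 2), ] * NA
  p <- rbind(rep(0.004 / 6, 6), rep(0.996 / 6, 6))
  expect_error(calibrate_thresholds(pool, p),
               class = "confbms_error_degenerate_branch")
  # zero-mass branch is allowed (left unreachable, no error)
  p0 <- rbind(rep(0, 6), rep(1 / 6, 6))
  thr <- calibrate_thresholds(pool, p0)
  resp <- assign_responses(pool$x1, pool$x2, "difference", thr, 0.07)
  expect_true(all(resp$decision == 2L))
})
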