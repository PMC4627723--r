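test_that("datasets round-trip through the delimited format", {
  dat <- simulate_subject("max", uniform_params(lapse = 0.02),
                          design_trials(experiment_design(n_trials = 40), seed = 91),
                          n_calibration = 1000, seed = 91)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(dat, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(dat))

  # property: random datasets round-trip losslessly
  for (r in 1:5) {
    rnd <- tibble::tibble(
      trial = 1:25,
      interval = sample(1:2, 25, TRUE),
      contrast = sample(default_contrasts(), 25, TRUE),
      decision = sample(1:2, 25, TRUE),
      confidence = sample(1:6, 25, TRUE)
    )
    p2 <- withr::local_tempfile(fileext = ".csv")
    write_dataset(rnd, p2)
    expect_equal(as.data.frame(read_dataset(p2)), as.data.frame(rnd))
  }
})

test_that("malformed datasets are rejected with row information", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial,interval,contrast,decision,confidence",
               "1,1,0.07,2,7"), path)
  expect_error(read_dataset(path), "confidence",
               class = "confbms_error_invalid_input")
  writeLines(c("trial,interval,contrast,decision,confidence",
               "1,3,0.07,2,4"), path)
  expect_error(read_dataset(path), class = "confbms_error_invalid_input")
  writeLines(c("trial,interval,contrast,decision,confidence",
               "1,1,0.08,2,4"), path)
  expect_error(read_dataset(path), "contrast",
               class = "confbms_error_invalid_input")
  # header-only file is an empty dataset, not an error
  writeLines("trial,interval,contrast,decision,confidence", path)
  expect_equal(nrow(read_dataset(path)), 0)
})

test_that("signed transforms are sign-coded bijections", {
  expect_identical(signed_confidence(1L, 3L), -3L)
  expect_identical(signed_confidence(2L, 3L), 3L)
  expect_equal(signed_contrast(1, 0.07), -0.07)
  expect_equal(signed_contrast(2, 0.15), 0.15)

  pairs <- tidyr::expand_grid(decision = 1:2, confidence = 1:6)
  sc <- signed_confidence(pairs$decision, pairs$confidence)
  expect_equal(sort(sc), c(-6:-1, 1:6))
  expect_equal(abs(sc), pairs$confidence)

  conds <- condition_grid()
  s8 <- signed_contrast(conds$interval, conds$contrast)
  expect_equal(length(unique(s8)), 8)
  expect_equal(abs(s8), conds$contrast)

  expect_error(signed_confidence(3L, 1L), class = "confbms_error_invalid_parameter")
  expect_error(signed_contrast(1, -0.1), class = "confbms_error_invalid_parameter")
})

test_that("theoretical confidence distributions are proper and ordered by spread", {
  dists <- lapply(c(difference = "difference", max = "max", bayes = "bayes"),
                  function(m) {
                    theoretical_confidence_distributions(m, uniform_params(),
                                                         n_per_condition = 12500,
                                                         seed = 92)
                  })
  for (d in dists) {
    sums <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(d), interval, contrast),
                             s = sum(prob), .groups = "drop")
    expect_equal(sums$s, rep(1, 8), tolerance = 1e-12)
  }
  spread <- vapply(dists, function(d) {
    sub <- d[d$contrast == 0.015 & d$interval == 2, ]
    sqrt(sum(sub$prob * sub$signed_confidence^2) -
           sum(sub$prob * sub$signed_confidence)^2)
  }, numeric(1))
  # narrowest to broadest: max, bayes, difference
  expect_lt(spread[["max"]], spread[["bayes"]])
  expect_lt(spread[["bayes"]], spread[["difference"]])
})

test_that("region maps reflect each model's geometry", {
  xs <- seq(-0.08, 0.2, length.out = 41)
  maps <- lapply(c(difference = "difference", max = "max", bayes = "bayes"),
                 function(m) {
                   confidence_region_map(m, uniform_params(), x1 = xs, x2 = xs,
                                         n_calibration = 4000, seed = 93)
                 })
  for (m in maps) {
    expect_true(all(m$signed_confidence %in% c(-6:-1, 1:6)))
  }
  # difference model: label is exactly a function of x2 - x1
  dm <- maps[["difference"]]
  key <- round(dm$x2 - dm$x1, 12)
  expect_true(all(tapply(dm$signed_confidence, key,
                         function(v) length(unique(v)) == 1)))
  # max model: within a decision, the label depends only on the chosen signal
  mm <- maps[["max"]]
  d2 <- mm[mm$decision == 2, ]
  expect_true(all(tapply(d2$signed_confidence, d2$x2,
                         function(v) length(unique(v)) == 1)))
  d1 <- mm[mm$decision == 1, ]
  expect_true(all(tapply(d1$signed_confidence, d1$x1,
                         function(v) length(unique(v)) == 1)))
  # bayes model: not a function of x2 - x1 alone
  bm <- maps[["bayes"]]
  keyb <- round(bm$x2 - bm$x1, 12)
  multi <- tapply(bm$signed_confidence, keyb, function(v) length(unique(v)) > 1)
  expect_true(any(multi))
})

test_that("plot builders return ggplot objects", {
  dist <- theoretical_confidence_distributions("max", uniform_params(),
                                               n_per_condition = 1000, seed = 94)
  expect_s3_class(autoplot(dist), "ggplot")
  rmap <- confidence_region_map("max", uniform_params(),
                                x1 = seq(-0.05, 0.1, length.out = 11),
                                x2 = seq(-0.05, 0.1, length.out = 11),
                                n_calibration = 1000, seed = 95)
  expect_s3_class(autoplot(rmap), "ggplot")
  ev <- tibble::tibble(subject = rep(c("a", "b"), each = 3),
                       model = rep(c("difference", "max", "bayes"), 2),
                       log_evidence = c(0, 1, 2, 0, 2, 3),
                       std_error = rep(0.1, 6))
  expect_s3_class(plot_evidence_differences(ev), "ggplot")
  expect_s3_class(plot_subject_differences(ev), "ggplot")
  bms <- random_effects_bms(ev, seed = 96)
  expect_s3_class(autoplot(bms), "ggplot")
  expect_equal(nrow(tidy(bms)), 3)
  expect_equal(glance(bms)$n_subjects, 2)
})

test_that("the pipeline is deterministic and complete", {
  params <- uniform_params(lapse = 0.02)
  conds <- design_trials(experiment_design(n_trials = 48), seed = 97)
  datasets <- list(
    s1 = simulate_subject("difference", params, conds, n_calibration = 800, seed = 97),
    s2 = simulate_subject("bayes", params, conds, n_calibration = 800, seed = 98)
  )
  out1 <- withr::local_tempdir()
  cfg <- run_config(models = c("difference", "bayes"), n_is_samples = 100,
                    n_runs = 2, n_per_condition = 400, seed = 99,
                    output_dir = out1)
  res <- run_pipeline(cfg, datasets)
  expect_equal(nrow(res$evidence), 4)  # 2 subjects x 2 models
  expect_equal(length(res$per_run), 4)
  expect_true(all(vapply(res$per_run, length, integer(1)) == 2))
  expect_true(all(file.exists(res$files)))

  # rerun with the same seed: bit-identical serialized outputs
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(models = c("difference", "bayes"), n_is_samples = 100,
                     n_runs = 2, n_per_condition = 400, seed = 99,
                     output_dir = out2)
  res2 <- run_pipeline(cfg2, datasets)
  expect_identical(readLines(res$files[1]), readLines(res2$files[1]))
  expect_identical(readLines(res$files[2]), readLines(res2$files[2]))

  # omitting a model omits it downstream
  cfg3 <- run_config(models = "bayes", n_is_samples = 50, n_runs = 2,
                     n_per_condition = 400, seed = 99)
  res3 <- run_pipeline(cfg3, datasets)
  expect_equal(unique(res3$evidence$model), "bayes")
  expect_equal(nrow(res3$fixed_effects), 1)

  # evidence estimates can be tidied / glanced
  est <- importance_evidence(datasets$s1, "difference", n_is_samples = 50,
                             n_runs = 2, n_per_condition = 400, seed = 100)
  expect_equal(nrow(tidy(est)), 2)
  expect_equal(glance(est)$n_runs, 2)
})
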