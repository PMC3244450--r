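test_that("effect calibration inverts the pipeline's estimators", {
  cfg <- generator_config(
    target_interference = tibble::tibble(
      arousal = c("high", "low", "high", "low"),
      block = c(1, 1, 2, 2),
      interference = 100
    ),
    target_adaptation = tibble::tibble(
      valence = c("negative", "positive", "negative", "positive"),
      block = c(1, 1, 2, 2),
      adaptation = 50
    )
  )
  eff <- calibrate_effects(cfg)
  expect_equal(unique(eff$gamma), 50)
  expect_equal(unique(eff$delta), 125)  # 100 + 50 * 0.5

  # zero adaptation target: delta equals the interference target
  cfg0 <- generator_config(
    target_adaptation = tibble::tibble(
      valence = rep(c("negative", "positive"), 2),
      block = rep(1:2, each = 2),
      adaptation = 0
    )
  )
  eff0 <- calibrate_effects(cfg0)
  merged <- dplyr::inner_join(eff0, cfg0$target_interference,
                              by = c("arousal", "block"))
  expect_equal(merged$delta, merged$interference)
})

test_that("default calibration reflects the four distinct study cells", {
  eff <- calibrate_effects(generator_config())
  b1 <- dplyr::filter(eff, block == 1)
  expect_equal(nrow(dplyr::distinct(b1, delta, gamma)), 4)
  expect_equal(
    b1$gamma[b1$valence == "negative"][1], 76
  )
  expect_equal(
    b1$delta[b1$valence == "positive" & b1$arousal == "high"],
    117 + 26 * 0.5
  )
})

test_that("cohorts are reproducible with the design's trial structure", {
  cfg <- generator_config(n_per_group = 3)
  t1 <- generate_cohort(cfg, seed = 8)
  t2 <- generate_cohort(cfg, seed = 8)
  expect_identical(t1, t2)
  counts <- dplyr::count(t1, subject, block)
  expect_true(all(counts$n == 32))
  expect_equal(dplyr::n_distinct(t1$subject), 12)
  expect_equal(sum(dplyr::count(t1, subject)$n), 12 * 64)
  # distractor frequency is binomial with p = 0.5
  expect_equal(mean(t1$distractor), 0.5, tolerance = 0.1)
})

test_that("a noise-free cohort is recovered exactly by the pipeline", {
  cfg <- noise_free_config()
  trials <- generate_cohort(cfg, seed = 17)
  expect_equal(sum(trials$error), 0L)
  expect_true(all(trials$rt <= 1400))
  kept <- filter_trials(trials)
  summaries <- subject_summaries(trials)
  eff <- calibrate_effects(cfg)
  merged <- summaries |>
    dplyr::inner_join(eff, by = c("valence", "arousal", "block"))
  # modulation recovers gamma exactly
  ok <- !is.na(merged$modulation)
  expect_gt(sum(ok), 0)
  expect_equal(merged$modulation[ok], merged$gamma[ok], tolerance = 1e-9)
  # interference equals delta - gamma * (realized share of retained
  # distractor trials whose raw predecessor was a distractor)
  realized <- kept |>
    dplyr::filter(.data$distractor) |>
    dplyr::group_by(subject, block) |>
    dplyr::summarise(share_prev = mean(prev_distractor), .groups = "drop")
  merged2 <- dplyr::inner_join(merged, realized, by = c("subject", "block"))
  expect_equal(
    merged2$interference,
    merged2$delta - merged2$gamma * merged2$share_prev,
    tolerance = 1e-9
  )
})

test_that("exclusion fractions track the configured rates", {
  cfg <- generator_config(n_per_group = 25)
  trials <- generate_cohort(cfg, seed = 23)
  log <- exclusion_log(filter_trials(trials), overall = TRUE)
  n <- log$n_total
  se <- function(p) 3 * sqrt(p * (1 - p) / n)
  expect_lt(abs(log$frac_outlier - cfg$outlier_rate),
            se(cfg$outlier_rate) + 0.005)
  # errors counted after outliers and block-initial trials, so the
  # fraction sits slightly below the raw rate
  expect_lt(log$frac_error, cfg$error_rate + se(cfg$error_rate))
  expect_gt(log$frac_error,
            cfg$error_rate * 0.9 - se(cfg$error_rate))
  # block-initial trials that are also lapses are counted as outliers,
  # so the fraction sits just under 2/64
  expect_lt(abs(log$frac_first_trial - 2 / 64), 0.005)
})

test_that("practice trials are generated distractor-free under block 0", {
  cfg <- generator_config(n_per_group = 2, include_practice = TRUE)
  trials <- generate_cohort(cfg, seed = 3)
  practice <- dplyr::filter(trials, block == 0)
  expect_equal(nrow(practice), 8 * 128)
  expect_false(any(practice$distractor))
  kept <- filter_trials(trials)
  expect_false(any(kept$block == 0))
  expect_equal(exclusion_log(kept, overall = TRUE)$practice, 8 * 128)
})

test_that("affect ratings follow the configured group means on the grid", {
  cfg <- generator_config(n_per_group = 40)
  ratings <- generate_affect_ratings(cfg, seed = 12)
  expect_true(all(ratings$valence_rating %in% 1:9))
  means <- ratings |>
    dplyr::group_by(valence) |>
    dplyr::summarise(v = mean(valence_rating))
  expect_gt(means$v[means$valence == "positive"],
            means$v[means$valence == "negative"])

  # zero spread puts every subject at the (rounded) group mean
  at <- cfg$affect_targets
  at$se_valence <- 0
  at$se_arousal <- 0
  cfg0 <- generator_config(n_per_group = 3, affect_targets = at)
  r0 <- generate_affect_ratings(cfg0, seed = 1)
  per_group <- r0 |>
    dplyr::group_by(valence, arousal) |>
    dplyr::summarise(n_distinct = dplyr::n_distinct(valence_rating),
                     .groups = "drop")
  expect_true(all(per_group$n_distinct == 1))

  # grid means outside 1-9 are rejected at construction
  bad <- cfg$affect_targets
  bad$mean_valence[1] <- 11
  expect_error(generator_config(affect_targets = bad), "1-9")
})

test_that("subject interference and modulation are independent by construction", {
  rs <- purrr::map_dbl(1:12, function(s) {
    trials <- generate_cohort(generator_config(n_per_group = 15), seed = s)
    interference_modulation_correlation(subject_summaries(trials))$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})
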