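test_that("the three exclusion rules remove the documented toy trials", {
  toy <- toy_block()
  kept <- filter_trials(toy)
  expect_equal(nrow(kept), 7)
  log <- exclusion_log(kept, overall = TRUE)
  expect_equal(log$outlier, 1L)
  expect_equal(log$first_trial, 1L)
  expect_equal(log$error, 1L)
  expect_equal(log$kept + log$outlier + log$first_trial + log$error +
                 log$practice, log$n_total)
})

test_that("overlapping violations are counted once, under the first rule", {
  toy <- toy_block()
  toy$rt[1] <- 1600      # block-initial AND outlier
  toy$error[4] <- TRUE   # outlier AND error
  kept <- filter_trials(toy)
  log <- exclusion_log(kept, overall = TRUE)
  expect_equal(log$outlier, 2L)      # trials 1 and 4
  expect_equal(log$first_trial, 0L)  # trial 1 already counted as outlier
  expect_equal(log$error, 1L)        # trial 7 only
  expect_equal(log$kept, 7L)
  expect_equal(log$kept + log$outlier + log$first_trial + log$error,
               log$n_total)
})

test_that("filtering is idempotent and the identity on clean tables", {
  clean <- toy_block() |>
    dplyr::mutate(rt = pmin(rt, 1000), error = FALSE) |>
    dplyr::filter(trial > 1)
  kept <- filter_trials(clean)
  expect_equal(nrow(kept), nrow(clean))
  log <- exclusion_log(kept, overall = TRUE)
  expect_equal(log$outlier + log$first_trial + log$error, 0L)
  twice <- filter_trials(kept)
  expect_equal(dplyr::select(twice, subject:error),
               dplyr::select(kept, subject:error))
})

test_that("per-subject accounting holds on a generated cohort", {
  trials <- generate_cohort(generator_config(n_per_group = 5), seed = 21)
  kept <- filter_trials(trials)
  log <- exclusion_log(kept)
  expect_true(all(
    log$kept + log$outlier + log$first_trial + log$error + log$practice ==
      log$n_total
  ))
  expect_equal(sum(log$n_total), nrow(trials))
  expect_equal(sum(log$kept), nrow(kept))
})

test_that("interference is the hand-computed difference of cell means", {
  trials <- tibble::tibble(
    subject = "s1", block = 1, trial = 2:5,
    distractor = c(TRUE, TRUE, FALSE, FALSE),
    rt = c(800, 820, 700, 720), error = FALSE
  )
  out <- interference(trials)
  expect_equal(out$interference, 100)
  expect_equal(out$rt_dis, 810)
  expect_equal(out$rt_no_dis, 710)
})

test_that("empty cells yield missing values with reasons, never zeros", {
  no_dis <- tibble::tibble(
    subject = "s1", block = 1, trial = 2:4,
    distractor = FALSE, rt = c(700, 710, 720), error = FALSE
  )
  out <- interference(no_dis)
  expect_true(is.na(out$interference))
  expect_equal(out$reason, "empty distractor cell")

  # distractor-present never follows distractor-present
  seq_tab <- tibble::tibble(
    subject = "s1", block = 1, trial = 1:8,
    distractor = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    rt = 700 + 1:8, error = FALSE
  )
  kept <- filter_trials(seq_tab)
  mod <- conflict_modulation(kept)
  expect_true(is.na(mod$modulation))
  expect_equal(mod$reason, "empty conditional cell")
})

test_that("previous-trial status comes from the raw sequence, not survivors", {
  # trial 3's predecessor (trial 2) is an outlier distractor trial; it
  # is excluded but must still count as a distractor-present predecessor
  tab <- tibble::tibble(
    subject = "s1", block = 1, trial = 1:9,
    distractor = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
    rt = c(700, 1500, 900, 700, 705, 890, 710, 905, 712),
    error = FALSE
  )
  kept <- filter_trials(tab)
  expect_false(2 %in% kept$trial)
  expect_true(kept$prev_distractor[kept$trial == 3])
  mod <- conflict_modulation(kept)
  expect_false(is.na(mod$modulation))
})

test_that("interference and modulation are invariant to RT shifts", {
  trials <- generate_cohort(generator_config(n_per_group = 2), seed = 31)
  base <- subject_summaries(trials)
  shifted <- dplyr::mutate(trials, rt = rt + 250)
  shifted_sum <- subject_summaries(shifted, rt_cutoff = 1650)
  expect_equal(shifted_sum$interference, base$interference + 0,
               tolerance = 1e-9)
  expect_equal(shifted_sum$modulation, base$modulation, tolerance = 1e-9)
})

test_that("subject-level correlation reports r, CI and p, and flags degeneracy", {
  summaries <- make_summaries(
    10,
    interference = function(n) rnorm(n, 100, 30),
    seed = 5
  )
  summaries$modulation <- summaries$interference  # perfect dependence
  out <- interference_modulation_correlation(summaries, block = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 40)

  summaries$modulation <- 50  # constant
  expect_warning(
    flat <- interference_modulation_correlation(summaries, block = 1),
    "Zero variance"
  )
  expect_true(flat$undefined)
  expect_true(is.na(flat$r))
})
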