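test_that("parameter validation enforces the model's ranges", {
  expect_s3_class(control_params(0.5, 0, 1), "control_params")
  expect_error(control_params(0, 0.5, 0.5), "lambda")
  expect_error(control_params(1, 0.5, 0.5), "lambda")
  expect_error(control_params(0.5, -0.1, 0.5), "beta")
  expect_error(control_params(0.5, 0.5, 1.2), "alpha")
})

test_that("a single control update follows the difference equation", {
  p <- control_params(0.5, 0.4, 0.8)
  expect_equal(update_control(0, 0, p), 0.2)
  # pure decay when beta = alpha = 0
  p0 <- control_params(0.3, 0, 0)
  expect_equal(update_control(c(1, 0.5, -2), c(0, 1, 0), p0),
               0.7 * c(1, 0.5, -2))
  # alpha * e + beta is a fixed point under constant conflict
  for (e in c(0, 1)) {
    p <- control_params(0.25, 0.3, 0.6)
    cstar <- p$alpha * e + p$beta
    expect_equal(update_control(cstar, e, p), cstar)
  }
  expect_error(update_control(0, 2, p), "0 or 1")
})

test_that("simulated trajectories match an independent loop implementation", {
  set.seed(42)
  for (i in 1:5) {
    p <- control_params(runif(1, 0.05, 0.95), runif(1), runif(1))
    c0 <- runif(1, -0.5, 0.5)
    traj <- simulate_run(p, n_trials = 400, p_conflict = runif(1, 0.2, 0.8),
                         initial_control = c0, seed = 1000 + i)
    expect_equal(
      traj$control,
      naive_trajectory(traj$conflict, p$lambda, p$beta, p$alpha, c0),
      tolerance = 1e-12
    )
  }
})

test_that("trajectories are reproducible and start at the initial control", {
  p <- control_params(0.4, 0.3, 0.5)
  t1 <- simulate_run(p, n_trials = 200, seed = 7)
  t2 <- simulate_run(p, n_trials = 200, seed = 7)
  expect_identical(t1$control, t2$control)
  expect_identical(t1$conflict, t2$conflict)
  expect_identical(t1$control[1], 0)
  # zero drive keeps control at zero for every trial
  t0 <- simulate_run(control_params(0.5, 0, 0), n_trials = 100, seed = 3)
  expect_true(all(t0$control == 0))
})

test_that("mean control averages every trial and mean adaptation needs both classes", {
  p <- control_params(0.5, 0, 0)
  traj <- simulate_run(p, n_trials = 50, seed = 1)
  expect_equal(mean_control(traj), 0)
  const <- tibble::tibble(conflict = rbinom(20, 1, 0.5),
                          control = rep(0.37, 20))
  expect_equal(mean_control(const), 0.37)
  # conflict cannot move control when alpha = 0 and the trajectory is
  # at its fixed point
  pa0 <- control_params(0.6, 0.4, 0)
  flat <- simulate_run(pa0, n_trials = 300, initial_control = 0.4, seed = 2)
  expect_equal(mean_adaptation(flat), 0)
  # degenerate two-trial sequence: only one previous-trial class
  degen <- tibble::tibble(conflict = c(1, 0), control = c(0, 0.5))
  expect_error(mean_adaptation(degen), "Degenerate")
})

test_that("run summaries agree with the closed-form expectations over seeds", {
  cells <- list(
    control_params(0.3, 0.2, 0.6),
    control_params(0.9, 0.3, 0.4),
    control_params(0.1, 0.6, 0.8)
  )
  n_seeds <- 50
  for (p in cells) {
    stats <- vapply(seq_len(n_seeds), function(s) {
      traj <- simulate_run(p, n_trials = 500, seed = 5000 + s)
      c(mean_control(traj), mean_adaptation(traj))
    }, numeric(2))
    mc <- stats[1, ]
    ma <- stats[2, ]
    se_mc <- sd(mc) / sqrt(n_seeds)
    se_ma <- sd(ma) / sqrt(n_seeds)
    expect_lt(
      abs(mean(mc) - expected_mean_control(p, n_trials = 500)), 3 * se_mc
    )
    expect_lt(abs(mean(ma) - expected_mean_adaptation(p)), 3 * se_ma)
  }
})

test_that("mean control is flat in lambda and adaptation flat in beta", {
  # lambda invariance of the stationary component of mean control,
  # tested on transient-corrected residuals at fixed (beta, alpha)
  lambdas <- seq(0.05, 0.95, 0.1)
  resid <- purrr::map_dfr(lambdas, function(l) {
    p <- control_params(l, 0.4, 0.6)
    purrr::map_dfr(1:8, function(s) {
      traj <- simulate_run(p, n_trials = 1000, seed = 100 * s + round(100 * l))
      tibble::tibble(
        lambda = l,
        resid = mean_control(traj) - expected_mean_control(p, 1000)
      )
    })
  })
  fit <- summary(lm(resid ~ lambda, data = resid))$coefficients
  expect_lt(abs(fit["lambda", "Estimate"]),
            3 * fit["lambda", "Std. Error"])

  betas <- seq(0.05, 0.95, 0.1)
  adapt <- purrr::map_dfr(betas, function(b) {
    p <- control_params(0.5, b, 0.6)
    purrr::map_dfr(1:8, function(s) {
      traj <- simulate_run(p, n_trials = 1000, seed = 7000 + 100 * s + round(100 * b))
      tibble::tibble(beta = b, ma = mean_adaptation(traj))
    })
  })
  fitb <- summary(lm(ma ~ beta, data = adapt))$coefficients
  expect_lt(abs(fitb["beta", "Estimate"]), 3 * fitb["beta", "Std. Error"])
})
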