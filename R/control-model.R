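#' Parameters of the conflict-monitoring control loop
#'
#' Bundles and validates the three parameters of the control update
#' equation: `lambda` (control adaptation, the weight of the previous
#' trial's conflict relative to the previous level of control), `beta`
#' (base-level control added at every step) and `alpha` (conflict gain,
#' the scaling applied to the raw binary conflict signal before it
#' enters the update).
#'
#' @param lambda Control-adaptation weight, strictly inside (0, 1).
#' @param beta Base-level control, in \[0, 1\].
#' @param alpha Conflict gain, in \[0, 1\].
#'
#' @return An object of class `control_params`: a named list with
#'   elements `lambda`, `beta`, `alpha`.
#' @examples
#' control_params(lambda = 0.5, beta = 0.4, alpha = 0.8)
#' @export
control_params <- function(lambda, beta, alpha) {
  stopifnot(
    is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
    is.numeric(beta), length(beta) == 1L, is.finite(beta),
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha)
  )
  if (lambda <= 0 || lambda >= 1) {
    stop("`lambda` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (beta < 0 || beta > 1) {
    stop("`beta` must lie in [0, 1].", call. = FALSE)
  }
  if (alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  structure(list(lambda = lambda, beta = beta, alpha = alpha),
            class = "control_params")
}

#' @export
print.control_params <- function(x, ...) {
  cat(sprintf(
    "<control_params> lambda = %g, beta = %g, alpha = %g\n",
    x$lambda, x$beta, x$alpha
  ))
  invisible(x)
}

#' One step of the control update equation
#'
#' Applies the conflict-monitoring difference equation
#' \deqn{C_t = (1 - \lambda)\, C_{t-1} + \lambda (\alpha E_{t-1} + \beta)}
#' where `e_prev` is the binary conflict indicator of the previous
#' trial. The update is deterministic and unclamped; with all
#' parameters in \[0, 1\] the recursion stays bounded.
#'
#' @param c_prev Control on the previous trial (numeric vector).
#' @param e_prev Conflict on the previous trial, each element 0 or 1
#'   (recycled against `c_prev`).
#' @param params A [control_params()] object.
#'
#' @return Numeric vector of updated control values.
#' @examples
#' update_control(0, 0, control_params(0.5, 0.4, 0.8)) # 0.2
#' @export
update_control <- function(c_prev, e_prev, params) {
  stopifnot(inherits(params, "control_params"), is.numeric(c_prev))
  if (!all(e_prev %in% c(0, 1))) {
    stop("`e_prev` must contain only 0 or 1.", call. = FALSE)
  }
  (1 - params$lambda) * c_prev +
    params$lambda * (params$alpha * e_prev + params$beta)
}

#' Simulate one run of the conflict-monitoring loop
#'
#' Draws an i.i.d. Bernoulli conflict sequence and iterates the control
#' update over it. Control starts at `initial_control` on trial 1; from
#' trial 2 on, each trial's control is the update of the previous
#' trial's control and conflict.
#'
#' @param params A [control_params()] object.
#' @param n_trials Number of trials (>= 2). Default 1000.
#' @param p_conflict Probability that a trial carries conflict, in
#'   \[0, 1\]. Default 0.5.
#' @param initial_control Control on the first trial. Default 0.
#' @param seed Optional integer seed; when supplied the run is fully
#'   reproducible.
#'
#' @return A tibble of class `ca_trajectory` with columns `trial`,
#'   `conflict` (0/1) and `control`, carrying the parameters and
#'   settings as attributes.
#' @examples
#' traj <- simulate_run(control_params(0.3, 0.2, 0.6), seed = 1)
#' mean_control(traj)
#' @export
simulate_run <- function(params, n_trials = 1000, p_conflict = 0.5,
                         initial_control = 0, seed = NULL) {
  stopifnot(inherits(params, "control_params"))
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 2) {
    stop("`n_trials` must be a single number >= 2.", call. = FALSE)
  }
  if (!is.numeric(p_conflict) || p_conflict < 0 || p_conflict > 1) {
    stop("`p_conflict` must lie in [0, 1].", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  conflict <- stats::rbinom(n_trials, 1L, p_conflict)
  control <- cpp_control_trajectory(
    conflict, params$lambda, params$beta, params$alpha, initial_control
  )
  out <- tibble::tibble(
    trial = seq_len(n_trials),
    conflict = conflict,
    control = control
  )
  structure(
    out,
    params = params,
    p_conflict = p_conflict,
    initial_control = initial_control,
    seed = seed,
    class = c("ca_trajectory", class(out))
  )
}

#' Mean level of control of a simulated run
#'
#' Arithmetic mean of the control values over all trials of the run,
#' including the first (initialization) trial.
#'
#' @param traj A `ca_trajectory` from [simulate_run()], or any data
#'   frame with a `control` column.
#' @return A single number.
#' @export
mean_control <- function(traj) {
  stopifnot(is.data.frame(traj), "control" %in% names(traj))
  if (nrow(traj) == 0L) stop("Empty trajectory.", call. = FALSE)
  mean(traj$control)
}

#' Mean control adaptation of a simulated run
#'
#' Difference in mean control between trials whose previous trial
#' carried conflict and trials whose previous trial did not
#' (post-conflict minus post-no-conflict, so that stronger adaptation
#' gives a larger positive value; its expectation is `lambda * alpha`).
#'
#' @inheritParams mean_control
#' @return A single number.
#' @export
mean_adaptation <- function(traj) {
  stopifnot(is.data.frame(traj), all(c("conflict", "control") %in% names(traj)))
  n <- nrow(traj)
  if (n < 2L) {
    stop("Adaptation needs at least 2 trials.", call. = FALSE)
  }
  prev <- traj$conflict[-n]
  post <- traj$control[-1]
  if (!any(prev == 1) || !any(prev == 0)) {
    stop(
      "Degenerate sequence: one previous-trial conflict class is empty.",
      call. = FALSE
    )
  }
  mean(post[prev == 1]) - mean(post[prev == 0])
}

#' Closed-form expectations of the run summaries
#'
#' `expected_mean_control()` is the exact expectation of the run's mean
#' control under i.i.d. Bernoulli conflict, including the
#' initialization transient:
#' \deqn{E[\bar C] = \mu + (c_0 - \mu)\frac{1 - (1-\lambda)^n}{n\lambda},
#'   \quad \mu = \beta + p\,\alpha,}
#' which reduces to the stationary value `beta + p_conflict * alpha`
#' for large `n_trials * lambda`. `expected_mean_adaptation()` is
#' `lambda * alpha`, exact at every horizon.
#'
#' @inheritParams simulate_run
#' @return A single number.
#' @export
expected_mean_control <- function(params, n_trials = 1000, p_conflict = 0.5,
                                  initial_control = 0) {
  stopifnot(inherits(params, "control_params"))
  mu <- params$beta + p_conflict * params$alpha
  mu + (initial_control - mu) *
    (1 - (1 - params$lambda)^n_trials) / (n_trials * params$lambda)
}

#' @rdname expected_mean_control
#' @export
expected_mean_adaptation <- function(params) {
  stopifnot(inherits(params, "control_params"))
  params$lambda * params$alpha
}
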