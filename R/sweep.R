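#' Parameter grid for the Monte Carlo sweep
#'
#' Builds the factorial grid of control-model parameters. The default
#' uses increments of 0.05: `lambda` in 0.05..0.95 (19 levels) and
#' `beta`, `alpha` in 0.05..1.00 (20 levels each), i.e. 7600 cells.
#' Zero levels of `beta`/`alpha` are excluded by default because they
#' make correlation statistics degenerate, but any strictly increasing
#' levels within the parameter ranges can be supplied.
#'
#' @param step Grid increment used for the default level sequences.
#' @param lambda,beta,alpha Optional explicit level sequences
#'   (strictly increasing; `lambda` inside (0, 1), `beta`/`alpha`
#'   inside \[0, 1\]).
#' @return A list of class `ca_grid` with elements `lambda`, `beta`,
#'   `alpha`.
#' @examples
#' g <- sweep_grid()
#' length(g$lambda) * length(g$beta) * length(g$alpha) # 7600
#' @export
sweep_grid <- function(step = 0.05, lambda = NULL, beta = NULL, alpha = NULL) {
  lambda <- lambda %||% seq(step, 1 - step, by = step)
  beta <- beta %||% seq(step, 1, by = step)
  alpha <- alpha %||% seq(step, 1, by = step)
  check_levels <- function(x, name, lo_open, hi_open) {
    if (!is.numeric(x) || length(x) < 1L || anyNA(x)) {
      stop(sprintf("`%s` levels must be numeric and non-missing.", name),
           call. = FALSE)
    }
    if (is.unsorted(x, strictly = TRUE)) {
      stop(sprintf("`%s` levels must be strictly increasing.", name),
           call. = FALSE)
    }
    lo_ok <- if (lo_open) all(x > 0) else all(x >= 0)
    hi_ok <- if (hi_open) all(x < 1) else all(x <= 1)
    if (!lo_ok || !hi_ok) {
      stop(sprintf("`%s` levels fall outside the parameter range.", name),
           call. = FALSE)
    }
  }
  check_levels(lambda, "lambda", TRUE, TRUE)
  check_levels(beta, "beta", FALSE, FALSE)
  check_levels(alpha, "alpha", FALSE, FALSE)
  structure(list(lambda = lambda, beta = beta, alpha = alpha),
            class = "ca_grid")
}

#' Monte Carlo sweep over the control-model parameter grid
#'
#' Runs the conflict-monitoring simulation once (or `n_reps` times,
#' averaging the two summaries) for every cell of the parameter grid
#' and records mean control and mean control adaptation. A master seed
#' spawns one child seed per cell and replicate, indexed by cell, so
#' the sweep is reproducible and independent of evaluation order; a
#' given cell's single-replicate result is identical to calling
#' [simulate_run()] with that cell's child seed.
#'
#' @param grid A [sweep_grid()].
#' @param n_trials Trials per simulated run. Default 1000.
#' @param p_conflict Conflict probability per trial. Default 0.5.
#' @param initial_control Control on the first trial. Default 0.
#' @param seed Master seed for the per-cell seed stream.
#' @param n_reps Replicate runs per cell whose summaries are averaged.
#'   Default 1. Correlation statistics computed from the sweep are
#'   much less noisy when cell summaries are averaged over replicates.
#'
#' @return A tibble of class `ca_sweep` with columns `lambda`, `beta`,
#'   `alpha`, `mean_control`, `mean_adaptation`; simulation settings
#'   are kept as attributes.
#' @examples
#' sw <- run_sweep(sweep_grid(step = 0.25), n_trials = 200, seed = 1)
#' @export
run_sweep <- function(grid = sweep_grid(), n_trials = 1000, p_conflict = 0.5,
                      initial_control = 0, seed = NULL, n_reps = 1) {
  stopifnot(inherits(grid, "ca_grid"), n_reps >= 1)
  cells <- tidyr::expand_grid(
    lambda = grid$lambda, beta = grid$beta, alpha = grid$alpha
  )
  n_cells <- nrow(cells)
  seeds <- child_seeds(n_cells * n_reps, master = seed)
  lam <- cells$lambda
  bet <- cells$beta
  alp <- cells$alpha
  mc <- numeric(n_cells)
  ma <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    acc_mc <- 0
    acc_ma <- 0
    for (r in seq_len(n_reps)) {
      set.seed(seeds[(i - 1L) * n_reps + r])
      conflict <- stats::rbinom(n_trials, 1L, p_conflict)
      s <- cpp_control_stats(conflict, lam[i], bet[i], alp[i],
                             initial_control)
      acc_mc <- acc_mc + s[1]
      acc_ma <- acc_ma + s[2]
    }
    mc[i] <- acc_mc / n_reps
    ma[i] <- acc_ma / n_reps
  }
  out <- tibble::tibble(
    lambda = lam, beta = bet, alpha = alp,
    mean_control = mc, mean_adaptation = ma
  )
  structure(
    out,
    n_trials = n_trials, p_conflict = p_conflict,
    initial_control = initial_control, seed = seed, n_reps = n_reps,
    class = c("ca_sweep", class(out))
  )
}

#' Correlation between mean control and mean adaptation across the
#' conflict-gain sweep
#'
#' For every (`lambda`, `beta`) pair, the Pearson correlation between
#' mean control and mean control adaptation across the `alpha` levels
#' of the sweep. Under the model both summaries are linear in `alpha`,
#' so pure variation of the conflict gain drives this correlation
#' towards 1.
#'
#' @param sweep A `ca_sweep` from [run_sweep()] (or a data frame with
#'   the same columns).
#' @return A tibble with one row per (`lambda`, `beta`): `n_alpha`,
#'   `r`, and `undefined` (TRUE when either series has zero variance,
#'   in which case `r` is NA rather than silently dropped).
#' @export
correlation_over_alpha <- function(sweep) {
  check_sweep(sweep)
  n_alpha <- dplyr::n_distinct(sweep$alpha)
  if (n_alpha < 3L) {
    stop("Need at least 3 alpha levels per (lambda, beta) cell.",
         call. = FALSE)
  }
  sweep |>
    dplyr::group_by(.data$lambda, .data$beta) |>
    dplyr::summarise(
      n_alpha = dplyr::n(),
      r = guarded_cor(.data$mean_control, .data$mean_adaptation),
      .groups = "drop"
    ) |>
    dplyr::mutate(undefined = is.na(.data$r))
}

#' Correlation across the (lambda, beta) grid at fixed conflict gain
#'
#' For every `alpha` level, the Pearson correlation between mean
#' control and mean control adaptation across all (`lambda`, `beta`)
#' cells. Mean control depends (in expectation) only on `beta` and
#' mean adaptation only on `lambda`, and the two vary independently on
#' a factorial grid, so these correlations are driven towards 0.
#'
#' @inheritParams correlation_over_alpha
#' @return A tibble with one row per `alpha` level: `n_cells`, `r`,
#'   `abs_r`, and `undefined` (zero-variance levels are flagged, not
#'   dropped).
#' @export
correlation_fixed_alpha <- function(sweep) {
  check_sweep(sweep)
  n_cells <- dplyr::n_distinct(sweep$lambda, sweep$beta)
  if (n_cells < 3L) {
    stop("Need at least 3 (lambda, beta) cells per alpha level.",
         call. = FALSE)
  }
  sweep |>
    dplyr::group_by(.data$alpha) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      r = guarded_cor(.data$mean_control, .data$mean_adaptation),
      .groups = "drop"
    ) |>
    dplyr::mutate(abs_r = abs(.data$r), undefined = is.na(.data$r))
}

check_sweep <- function(sweep) {
  need <- c("lambda", "beta", "alpha", "mean_control", "mean_adaptation")
  if (!is.data.frame(sweep) || !all(need %in% names(sweep))) {
    stop("`sweep` must contain columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  invisible(sweep)
}

# Pearson r that returns NA (instead of erroring or NaN-ing) on
# zero-variance input; callers surface the NA as an `undefined` flag.
guarded_cor <- function(x, y) {
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}
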