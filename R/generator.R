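#' Configuration of the synthetic cohort generator
#'
#' Describes a pop-out distractor experiment with a 2 (valence) x
#' 2 (arousal) between-subject design, two 32-trial blocks per
#' subject, and a task-irrelevant distractor on half the trials. The
#' default effect targets are the study conditions the generator
#' emulates: block-1 interference of 117 ms (high arousal) vs 83 ms
#' (low arousal) falling to 51 ms in block 2 for both, and block-1
#' conflict-driven modulation of 76 ms (negative valence) vs 26 ms
#' (positive valence) falling to -3 ms in block 2.
#'
#' @param n_per_group Subjects per valence x arousal group. Default 25
#'   (a 100-subject cohort).
#' @param blocks Number of experimental blocks. Default 2.
#' @param trials_per_block Trials per block. Default 32.
#' @param p_distractor Probability that a trial contains the
#'   distractor. Default 0.5.
#' @param baseline_mu Mean baseline RT in ms. Default 700.
#' @param baseline_sd Between-subject SD of the baseline in ms.
#'   Default 80.
#' @param sigma,tau Trial noise is ex-Gaussian: Normal(0, `sigma`) plus
#'   Exponential with mean `tau`, both in ms. Defaults 60 and 60.
#' @param error_rate Probability of an error on any trial. Default
#'   0.022.
#' @param outlier_rate Probability that a trial is an attentional
#'   lapse whose RT falls beyond the 1400 ms analysis window (drawn as
#'   1500 ms + Exponential(mean 300)). Lapses are independent of the
#'   distractor factor. Default 0.039.
#' @param subject_sd_interference,subject_sd_adaptation Between-subject
#'   SDs (ms) of the distractor-cost and sequential-adaptation effects;
#'   the two subject effects are drawn independently, so subject-level
#'   interference and modulation are uncorrelated by construction.
#'   Defaults 40 and 40.
#' @param target_interference Data frame `arousal`, `block`,
#'   `interference` (ms) giving the interference the pipeline should
#'   recover per arousal level and block.
#' @param target_adaptation Data frame `valence`, `block`,
#'   `adaptation` (ms) giving the conflict-driven modulation to
#'   recover per valence level and block.
#' @param affect_targets Data frame `valence`, `arousal`,
#'   `mean_valence`, `se_valence`, `mean_arousal`, `se_arousal` with
#'   the affect-grid rating distribution per group (1-9 scale; the SEs
#'   refer to groups of `n_per_group` subjects).
#' @param include_practice If TRUE, also generate distractor-free
#'   practice trials (block 0). Default FALSE.
#' @param practice_trials Number of practice trials when generated.
#'   Default 128 (four 32-trial blocks' worth).
#'
#' @return A list of class `ca_config`.
#' @examples
#' cfg <- generator_config(n_per_group = 5)
#' calibrate_effects(cfg)
#' @export
generator_config <- function(n_per_group = 25,
                             blocks = 2,
                             trials_per_block = 32,
                             p_distractor = 0.5,
                             baseline_mu = 700,
                             baseline_sd = 80,
                             sigma = 60,
                             tau = 60,
                             error_rate = 0.022,
                             outlier_rate = 0.039,
                             subject_sd_interference = 40,
                             subject_sd_adaptation = 40,
                             target_interference = NULL,
                             target_adaptation = NULL,
                             affect_targets = NULL,
                             include_practice = FALSE,
                             practice_trials = 128) {
  target_interference <- target_interference %||% tibble::tribble(
    ~arousal, ~block, ~interference,
    "high",   1,      117,
    "low",    1,      83,
    "high",   2,      51,
    "low",    2,      51
  )
  target_adaptation <- target_adaptation %||% tibble::tribble(
    ~valence,   ~block, ~adaptation,
    "negative", 1,      76,
    "positive", 1,      26,
    "negative", 2,      -3,
    "positive", 2,      -3
  )
  affect_targets <- affect_targets %||% tibble::tribble(
    ~valence,   ~arousal, ~mean_valence, ~se_valence, ~mean_arousal, ~se_arousal,
    "positive", "high",   6.69,          0.34,        6.00,          0.36,
    "negative", "high",   4.50,          0.45,        5.54,          0.45,
    "positive", "low",    6.96,          0.32,        3.64,          0.43,
    "negative", "low",    4.24,          0.47,        3.76,          0.33
  )
  cfg <- list(
    n_per_group = n_per_group, blocks = blocks,
    trials_per_block = trials_per_block, p_distractor = p_distractor,
    baseline_mu = baseline_mu, baseline_sd = baseline_sd,
    sigma = sigma, tau = tau, error_rate = error_rate,
    outlier_rate = outlier_rate,
    subject_sd_interference = subject_sd_interference,
    subject_sd_adaptation = subject_sd_adaptation,
    target_interference = tibble::as_tibble(target_interference),
    target_adaptation = tibble::as_tibble(target_adaptation),
    affect_targets = tibble::as_tibble(affect_targets),
    include_practice = include_practice,
    practice_trials = practice_trials
  )
  validate_config(cfg)
  structure(cfg, class = "ca_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_per_group >= 1, cfg$blocks >= 1, cfg$trials_per_block >= 2,
    cfg$practice_trials >= 2
  )
  for (p in c("p_distractor", "error_rate", "outlier_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(sprintf("`%s` must lie in [0, 1].", p), call. = FALSE)
    }
  }
  for (s in c("baseline_sd", "sigma", "tau", "subject_sd_interference",
              "subject_sd_adaptation")) {
    if (cfg[[s]] < 0) stop(sprintf("`%s` must be >= 0.", s), call. = FALSE)
  }
  blocks <- seq_len(cfg$blocks)
  ti <- cfg$target_interference
  ta <- cfg$target_adaptation
  need_i <- tidyr::expand_grid(arousal = c("high", "low"), block = blocks)
  need_a <- tidyr::expand_grid(valence = c("negative", "positive"),
                               block = blocks)
  if (nrow(dplyr::anti_join(need_i, ti, by = c("arousal", "block"))) > 0 ||
      anyNA(ti$interference)) {
    stop("`target_interference` needs a finite value for every arousal x block.",
         call. = FALSE)
  }
  if (nrow(dplyr::anti_join(need_a, ta, by = c("valence", "block"))) > 0 ||
      anyNA(ta$adaptation)) {
    stop("`target_adaptation` needs a finite value for every valence x block.",
         call. = FALSE)
  }
  at <- cfg$affect_targets
  if (any(at$mean_valence < 1 | at$mean_valence > 9 |
            at$mean_arousal < 1 | at$mean_arousal > 9)) {
    stop("Affect-grid means must lie on the 1-9 grid.", call. = FALSE)
  }
  invisible(cfg)
}

#' Generative effect sizes implied by the pipeline targets
#'
#' Inverts the pipeline's estimators: the sequential term reduces the
#' distractor cost only after distractor-present trials, so measured
#' interference is `delta - gamma * p_distractor` and measured
#' modulation is `gamma`. Hence `gamma` equals the adaptation target
#' of the cell's valence level and `delta` equals its interference
#' target plus `gamma * p_distractor`.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per valence x arousal x block:
#'   `delta` (generative distractor cost, ms) and `gamma` (generative
#'   sequential reduction, ms).
#' @export
calibrate_effects <- function(config) {
  stopifnot(inherits(config, "ca_config"))
  tidyr::expand_grid(
    valence = c("negative", "positive"),
    arousal = c("low", "high"),
    block = seq_len(config$blocks)
  ) |>
    dplyr::inner_join(config$target_adaptation, by = c("valence", "block")) |>
    dplyr::inner_join(config$target_interference, by = c("arousal", "block")) |>
    dplyr::mutate(
      gamma = .data$adaptation,
      delta = .data$interference + .data$gamma * config$p_distractor
    ) |>
    dplyr::select("valence", "arousal", "block", "delta", "gamma")
}

subject_frame <- function(config) {
  groups <- tidyr::expand_grid(
    valence = c("negative", "positive"),
    arousal = c("low", "high")
  )
  n_subj <- nrow(groups) * config$n_per_group
  tibble::tibble(
    subject = sprintf("s%03d", seq_len(n_subj)),
    valence = rep(groups$valence, each = config$n_per_group),
    arousal = rep(groups$arousal, each = config$n_per_group)
  )
}

#' Generate a synthetic trial-level cohort
#'
#' Simulates RTs for every subject and trial of the configured design.
#' For subject s with baseline `b_s` and (subject-specific) effects
#' `delta_s`, `gamma_s`, trial t of a block has
#' `rt = b_s + delta_s * D_t - gamma_s * D_t * D_(t-1) + noise`, with
#' `D_t` the i.i.d. Bernoulli distractor indicator (`D_0 = 0`),
#' ex-Gaussian trial noise, and a small fraction of attentional-lapse
#' trials whose RT falls beyond the 1400 ms analysis window. Error
#' flags are i.i.d. Bernoulli. Subject effect deviations are drawn
#' once per subject (shared across blocks) and independently for the
#' two effects, and each subject's distractor cost is calibrated
#' against that subject's own sequential effect
#' (`delta_s = interference target + dev + p_distractor * gamma_s`),
#' which keeps measured interference and modulation uncorrelated by
#' construction.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed; the same seed reproduces the
#'   table exactly.
#' @return A tibble with columns `subject`, `valence`, `arousal`,
#'   `block` (0 = practice when enabled), `trial`, `distractor`
#'   (logical), `rt` (ms), `error` (logical).
#' @examples
#' trials <- generate_cohort(generator_config(n_per_group = 2), seed = 1)
#' dplyr::count(trials, block)
#' @export
generate_cohort <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "ca_config"))
  if (!is.null(seed)) set.seed(seed)
  subjects <- subject_frame(config)
  n_subj <- nrow(subjects)
  subjects$baseline <- stats::rnorm(n_subj, config$baseline_mu,
                                    config$baseline_sd)
  subjects$dev_interference <- stats::rnorm(n_subj, 0,
                                            config$subject_sd_interference)
  subjects$dev_adaptation <- stats::rnorm(n_subj, 0,
                                          config$subject_sd_adaptation)
  effects <- calibrate_effects(config)
  trials <- tidyr::expand_grid(
    subject = subjects$subject,
    block = seq_len(config$blocks),
    trial = seq_len(config$trials_per_block)
  ) |>
    dplyr::left_join(subjects, by = "subject") |>
    dplyr::left_join(effects, by = c("valence", "arousal", "block"))
  n <- nrow(trials)
  trials$distractor <- stats::rbinom(n, 1L, config$p_distractor) == 1L
  trials <- trials |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::mutate(
      prev = dplyr::lag(.data$distractor, default = FALSE)
    ) |>
    dplyr::ungroup()
  noise <- stats::rnorm(n, 0, config$sigma)
  if (config$tau > 0) noise <- noise + stats::rexp(n, 1 / config$tau)
  # The subject's distractor cost is calibrated against the subject's
  # own sequential effect (delta_s = interference target + dev_i +
  # p * gamma_s): the sequential term lowers measured interference by
  # p * gamma_s, so compensating per subject keeps the interference a
  # subject measures independent of that subject's adaptation, as well
  # as centered on the cell target.
  gamma_s <- trials$gamma + trials$dev_adaptation
  delta_s <- trials$delta + trials$dev_interference +
    trials$dev_adaptation * config$p_distractor
  rt <- trials$baseline +
    delta_s * trials$distractor -
    gamma_s * trials$distractor * trials$prev +
    noise
  lapse <- stats::rbinom(n, 1L, config$outlier_rate) == 1L
  if (any(lapse)) {
    rt[lapse] <- 1500 + stats::rexp(sum(lapse), 1 / 300)
  }
  trials$rt <- pmax(rt, 1)
  trials$error <- stats::rbinom(n, 1L, config$error_rate) == 1L
  out <- trials |>
    dplyr::select("subject", "valence", "arousal", "block", "trial",
                  "distractor", "rt", "error")
  if (config$include_practice) {
    np <- config$practice_trials
    pnoise <- stats::rnorm(n_subj * np, 0, config$sigma)
    if (config$tau > 0) pnoise <- pnoise + stats::rexp(n_subj * np,
                                                       1 / config$tau)
    prt <- rep(subjects$baseline, each = np) + pnoise
    plapse <- stats::rbinom(n_subj * np, 1L, config$outlier_rate) == 1L
    if (any(plapse)) prt[plapse] <- 1500 + stats::rexp(sum(plapse), 1 / 300)
    practice <- tibble::tibble(
      subject = rep(subjects$subject, each = np),
      valence = rep(subjects$valence, each = np),
      arousal = rep(subjects$arousal, each = np),
      block = 0,
      trial = rep(seq_len(np), times = n_subj),
      distractor = FALSE,
      rt = pmax(prt, 1),
      error = stats::rbinom(n_subj * np, 1L, config$error_rate) == 1L
    )
    out <- dplyr::bind_rows(practice, out)
  }
  dplyr::arrange(out, .data$subject, .data$block, .data$trial)
}

#' Generate affect-grid ratings for a cohort
#'
#' One valence and one arousal self-report rating per subject on the
#' 9 x 9 affect grid, drawn from the configured group means (the SDs
#' are reconstructed from the configured group SEs and group size),
#' rounded to the grid and truncated to 1-9.
#'
#' @inheritParams generate_cohort
#' @return A tibble: `subject`, `valence`, `arousal`,
#'   `valence_rating`, `arousal_rating`.
#' @export
generate_affect_ratings <- function(config = generator_config(),
                                    seed = NULL) {
  stopifnot(inherits(config, "ca_config"))
  if (!is.null(seed)) set.seed(seed)
  subjects <- subject_frame(config) |>
    dplyr::left_join(config$affect_targets, by = c("valence", "arousal"))
  n <- nrow(subjects)
  sd_scale <- sqrt(config$n_per_group)
  vr <- stats::rnorm(n, subjects$mean_valence,
                     subjects$se_valence * sd_scale)
  ar <- stats::rnorm(n, subjects$mean_arousal,
                     subjects$se_arousal * sd_scale)
  subjects |>
    dplyr::mutate(
      valence_rating = pmin(9, pmax(1, round(vr))),
      arousal_rating = pmin(9, pmax(1, round(ar)))
    ) |>
    dplyr::select("subject", "valence", "arousal", "valence_rating",
                  "arousal_rating")
}
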