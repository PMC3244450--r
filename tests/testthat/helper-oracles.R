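# Independent oracles and fixture builders used across the suite.

# Naive loop re-implementation of the control recursion, kept separate
# from the package's compiled path on purpose.
naive_trajectory <- function(conflict, lambda, beta, alpha, c0 = 0) {
  n <- length(conflict)
  C <- numeric(n)
  C[1] <- c0
  for (t in seq_len(n)[-1]) {
    C[t] <- (1 - lambda) * C[t - 1] + lambda * (alpha * conflict[t - 1] + beta)
  }
  C
}

naive_mean_adaptation <- function(conflict, control) {
  n <- length(conflict)
  prev <- conflict[-n]
  post <- control[-1]
  mean(post[prev == 1]) - mean(post[prev == 0])
}

# Textbook sums-of-squares solution of the 2 (between) x 2 (between) x
# 2 (within) split-plot design, for balanced data. Returns F values
# keyed by effect.
handworked_split_plot <- function(df) {
  y <- df$value
  M <- mean(y)
  ss <- function(means, n_obs) sum(n_obs * (means - M)^2)
  agg <- function(...) {
    m <- tapply(df$value, list(...), mean)
    n <- tapply(df$value, list(...), length)
    list(m = as.vector(m), n = as.vector(n))
  }
  subj <- agg(df$subject)
  v <- agg(df$valence)
  a <- agg(df$arousal)
  b <- agg(df$block)
  va <- agg(df$valence, df$arousal)
  vb <- agg(df$valence, df$block)
  ab <- agg(df$arousal, df$block)
  vab <- agg(df$valence, df$arousal, df$block)

  ss_subject <- ss(subj$m, subj$n)
  ss_v <- ss(v$m, v$n)
  ss_a <- ss(a$m, a$n)
  ss_va <- ss(va$m, va$n) - ss_v - ss_a
  ss_err_between <- ss_subject - ss_v - ss_a - ss_va
  ss_b <- ss(b$m, b$n)
  ss_vb <- ss(vb$m, vb$n) - ss_v - ss_b
  ss_ab <- ss(ab$m, ab$n) - ss_a - ss_b
  ss_vab <- ss(vab$m, vab$n) - ss_v - ss_a - ss_b - ss_va - ss_vb - ss_ab
  ss_total <- sum((y - M)^2)
  ss_err_within <- ss_total - ss_subject - ss_b - ss_vb - ss_ab - ss_vab

  n_subj <- length(subj$m)
  df_err <- n_subj - 4
  f <- function(ss_eff, ss_err) (ss_eff / 1) / (ss_err / df_err)
  list(
    F = c(
      valence = f(ss_v, ss_err_between),
      arousal = f(ss_a, ss_err_between),
      `valence:arousal` = f(ss_va, ss_err_between),
      block = f(ss_b, ss_err_within),
      `valence:block` = f(ss_vb, ss_err_within),
      `arousal:block` = f(ss_ab, ss_err_within),
      `valence:arousal:block` = f(ss_vab, ss_err_within)
    ),
    df_error = df_err,
    ss_error_between = ss_err_between,
    ss_error_within = ss_err_within
  )
}

# Fixed 8-subject split-plot example (2 subjects per group, 2 blocks).
eight_subject_example <- function() {
  tidyr::expand_grid(
    valence = c("negative", "positive"),
    arousal = c("low", "high"),
    rep = 1:2,
    block = 1:2
  ) |>
    dplyr::mutate(
      subject = paste0(substr(valence, 1, 1), substr(arousal, 1, 1), rep),
      value = c(
        112, 64, 98, 71, 131, 80, 125, 58,
        96, 47, 88, 60, 72, 66, 81, 49
      )
    ) |>
    dplyr::select(subject, valence, arousal, block, value)
}

# Ten-trial single-block toy table: trial 1 (block-initial), trial 4
# (outlier) and trial 7 (error) violate one rule each.
toy_block <- function() {
  tibble::tibble(
    subject = "a",
    valence = "negative",
    arousal = "high",
    block = 1,
    trial = 1:10,
    distractor = rep(c(TRUE, FALSE), 5),
    rt = c(700, 710, 720, 1500, 730, 740, 750, 760, 770, 780),
    error = c(rep(FALSE, 6), TRUE, rep(FALSE, 3))
  )
}

# Noise-free generator settings: every RT is an exact sum of baseline
# and calibrated effects.
noise_free_config <- function(n_per_group = 2) {
  generator_config(
    n_per_group = n_per_group,
    baseline_sd = 0, sigma = 0, tau = 0,
    error_rate = 0, outlier_rate = 0,
    subject_sd_interference = 0, subject_sd_adaptation = 0
  )
}

# Subject-summary table built directly (no trials), for ANOVA and
# correlation tests.
make_summaries <- function(n_per_group, interference, modulation = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(
    valence = c("negative", "positive"),
    arousal = c("low", "high"),
    rep = seq_len(n_per_group),
    block = 1:2
  )
  grid$subject <- paste0(grid$valence, "_", grid$arousal, "_", grid$rep)
  grid$interference <- interference(nrow(grid))
  if (!is.null(modulation)) grid$modulation <- modulation(nrow(grid))
  dplyr::select(grid, -rep)
}
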