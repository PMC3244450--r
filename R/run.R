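#' End-to-end analysis of a trial table
#'
#' Runs the full behavioral workflow on real or synthetic data:
#' exclusion rules, per-subject interference and conflict-driven
#' modulation, mixed-design ANOVAs for both RT measures and their
#' error-rate analogues, the subject-level interference-modulation
#' correlation, and the three-condition dissociability verdict. The
#' factor p-values entering the verdict are the block-1 simple main
#' effects of valence and arousal (the block in which the affect
#' manipulation is expected to act), and the correlation is computed
#' in the same block.
#'
#' @param trials A raw trial table; when `NULL`, a cohort is generated
#'   from `config` with `seed`.
#' @param config A [generator_config()] used when `trials` is `NULL`.
#' @param seed Seed for the generated cohort.
#' @param alpha Significance threshold for the dissociability
#'   decisions. Default 0.05.
#' @param block Block used for the dissociability evidence. Default 1.
#' @param rt_cutoff Outlier threshold in ms. Default 1400.
#'
#' @return A list of class `ca_report`: `seed`, `exclusions` (overall
#'   and per subject), `summaries`, `anova` (one [factorial_summary()]
#'   per measure), `correlation`, `factor_effects`, `dissociability`.
#' @examples
#' rep <- run_end_to_end(config = generator_config(n_per_group = 6), seed = 3)
#' rep$dissociability$verdict
#' @export
run_end_to_end <- function(trials = NULL, config = generator_config(),
                           seed = NULL, alpha = 0.05, block = 1,
                           rt_cutoff = 1400) {
  if (is.null(trials)) {
    trials <- generate_cohort(config, seed = seed)
  }
  check_trials(trials, need = c("subject", "valence", "arousal", "block",
                                "trial", "distractor", "rt", "error"))
  summaries <- subject_summaries(trials, rt_cutoff = rt_cutoff)
  anovas <- purrr::map(
    rlang::set_names(c("interference", "modulation", "error_interference",
                       "error_modulation")),
    function(m) factorial_summary(summaries, m)
  )
  correlation <- interference_modulation_correlation(summaries, block = block)
  blk <- as.character(block)
  factor_effects <- purrr::map_dfr(
    c(interference = "interference", modulation = "modulation"),
    function(m) {
      anovas[[m]]$simple_effects |>
        dplyr::filter(.data$block == blk,
                      .data$effect %in% c("valence", "arousal")) |>
        dplyr::transmute(factor = .data$effect, p_value = .data$p_value)
    },
    .id = "measure"
  ) |>
    dplyr::select("factor", "measure", "p_value")
  if (is.na(correlation$r)) {
    stop("Dissociability verdict needs a defined correlation.",
         call. = FALSE)
  }
  dissociability <- dissociability_check(
    factor_effects, r = correlation$r, r_p_value = correlation$p_value,
    alpha = alpha
  )
  structure(
    list(
      seed = seed,
      alpha = alpha,
      block = block,
      exclusions = list(
        overall = exclusion_log(summaries_with_log(summaries), overall = TRUE),
        per_subject = exclusion_log(summaries_with_log(summaries))
      ),
      summaries = summaries,
      anova = anovas,
      correlation = correlation,
      factor_effects = factor_effects,
      dissociability = dissociability
    ),
    class = "ca_report"
  )
}

# subject_summaries() carries the exclusion log; exclusion_log() wants
# the attribute holder.
summaries_with_log <- function(summaries) {
  structure(list(), exclusion_log = attr(summaries, "exclusion_log"))
}

#' @export
print.ca_report <- function(x, ...) {
  cat("End-to-end conflict-adaptation analysis\n")
  ov <- x$exclusions$overall
  cat(sprintf(
    "  trials: %d total; excluded %.1f%% outliers, %.1f%% block-initial, %.1f%% errors\n",
    ov$n_total, 100 * ov$frac_outlier, 100 * ov$frac_first_trial,
    100 * ov$frac_error
  ))
  cat(sprintf("  subjects: %d\n", dplyr::n_distinct(x$summaries$subject)))
  cat(sprintf("  block-%s interference-modulation r = %.3f (p = %.3f)\n",
              x$block, x$correlation$r, x$correlation$p_value))
  print(x$dissociability)
  invisible(x)
}

#' @export
glance.ca_report <- function(x, ...) {
  tibble::tibble(
    n_subjects = dplyr::n_distinct(x$summaries$subject),
    n_trials = x$exclusions$overall$n_total,
    r = x$correlation$r,
    r_p_value = x$correlation$p_value,
    dissociable = x$dissociability$verdict
  )
}
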