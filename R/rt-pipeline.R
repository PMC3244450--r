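#' Trial-level exclusion rules
#'
#' Removes outlier trials (RT above `rt_cutoff`), the first trial of
#' each block, and error trials. Each excluded trial is counted under
#' the first rule it violates, in that order (with a leading
#' "practice" category for block-0 trials when present), so per-rule
#' counts plus survivors always add up to the total. Before filtering,
#' each trial is annotated with the distractor status of its
#' predecessor in the raw sequence (`prev_distractor`), so later
#' sequence-conditioned measures refer to the original trial order
#' even when the predecessor itself was excluded.
#'
#' @param trials Data frame with at least `subject`, `block`, `trial`,
#'   `distractor`, `rt`, `error` (as produced by [generate_cohort()]
#'   or [read_trials()]).
#' @param rt_cutoff Outlier threshold in ms. Default 1400.
#'
#' @return The surviving trials as a tibble, with `prev_distractor`
#'   added and the exclusion log attached as attribute
#'   `"exclusion_log"` (see [exclusion_log()]).
#' @examples
#' trials <- generate_cohort(generator_config(n_per_group = 2), seed = 1)
#' kept <- filter_trials(trials)
#' exclusion_log(kept)
#' @export
filter_trials <- function(trials, rt_cutoff = 1400) {
  check_trials(trials)
  if (nrow(trials) == 0L) stop("Empty trial table.", call. = FALSE)
  annotated <- annotate_previous(trials)
  annotated <- annotated |>
    dplyr::mutate(
      .rule = dplyr::case_when(
        .data$block == 0 ~ "practice",
        .data$rt > rt_cutoff ~ "outlier",
        .data$trial == 1 ~ "first_trial",
        .data$error ~ "error",
        TRUE ~ "kept"
      )
    )
  log <- annotated |>
    dplyr::count(.data$subject, .data$.rule) |>
    tidyr::pivot_wider(
      names_from = ".rule", values_from = "n", values_fill = 0L
    )
  for (col in c("practice", "outlier", "first_trial", "error", "kept")) {
    if (!col %in% names(log)) log[[col]] <- 0L
  }
  log <- log |>
    dplyr::mutate(
      n_total = .data$practice + .data$outlier + .data$first_trial +
        .data$error + .data$kept
    ) |>
    dplyr::select("subject", "n_total", "practice", "outlier",
                  "first_trial", "error", "kept") |>
    dplyr::mutate(
      frac_outlier = .data$outlier / .data$n_total,
      frac_first_trial = .data$first_trial / .data$n_total,
      frac_error = .data$error / .data$n_total
    )
  kept <- annotated |>
    dplyr::filter(.data$.rule == "kept") |>
    dplyr::select(-".rule")
  structure(kept, exclusion_log = log, rt_cutoff = rt_cutoff,
            class = class(kept))
}

#' @rdname filter_trials
#' @param x A filtered trial table from [filter_trials()].
#' @param overall If TRUE, collapse the per-subject log into one row of
#'   overall counts and fractions.
#' @export
exclusion_log <- function(x, overall = FALSE) {
  log <- attr(x, "exclusion_log")
  if (is.null(log)) {
    stop("No exclusion log attached; did this come from filter_trials()?",
         call. = FALSE)
  }
  if (!overall) return(log)
  log |>
    dplyr::summarise(dplyr::across(
      c("n_total", "practice", "outlier", "first_trial", "error", "kept"),
      sum
    )) |>
    dplyr::mutate(
      frac_outlier = .data$outlier / .data$n_total,
      frac_first_trial = .data$first_trial / .data$n_total,
      frac_error = .data$error / .data$n_total
    )
}

# Distractor status of the preceding trial in the raw sequence
# (trial - 1 within subject x block); NA for block-initial trials,
# which the exclusion rules drop anyway.
annotate_previous <- function(trials) {
  if ("prev_distractor" %in% names(trials)) return(tibble::as_tibble(trials))
  trials |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$subject, .data$block, .data$trial) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::mutate(prev_distractor = dplyr::lag(.data$distractor)) |>
    dplyr::ungroup()
}

check_trials <- function(trials, need = c("subject", "block", "trial",
                                          "distractor", "rt", "error")) {
  if (!is.data.frame(trials) || !all(need %in% names(trials))) {
    stop("Trial table must have columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  if (any(!is.finite(trials$rt)) || any(trials$rt <= 0)) {
    stop("All RTs must be finite and positive.", call. = FALSE)
  }
  invisible(trials)
}

#' Distractor interference per subject and block
#'
#' Mean RT on distractor-present trials minus mean RT on
#' distractor-absent trials, per subject x block, computed from an
#' already filtered trial table. Subjects x blocks in which either
#' cell is empty get `NA` with a reason, never an imputed 0.
#'
#' @param trials A filtered trial table (see [filter_trials()]).
#' @return A tibble with one row per subject x block: `rt_dis`,
#'   `rt_no_dis`, `interference` (ms), cell counts `n_dis`,
#'   `n_no_dis`, and `reason` (NA when defined).
#' @export
interference <- function(trials) {
  check_trials(trials)
  trials |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(
      n_dis = sum(.data$distractor),
      n_no_dis = sum(!.data$distractor),
      rt_dis = mean(.data$rt[.data$distractor]),
      rt_no_dis = mean(.data$rt[!.data$distractor]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      interference = dplyr::if_else(
        .data$n_dis >= 1L & .data$n_no_dis >= 1L,
        .data$rt_dis - .data$rt_no_dis,
        NA_real_
      ),
      reason = dplyr::if_else(
        .data$n_dis >= 1L & .data$n_no_dis >= 1L,
        NA_character_, "empty distractor cell"
      )
    )
}

#' Conflict-driven modulation of interference per subject and block
#'
#' Interference restricted to trials following distractor-absent
#' trials minus interference restricted to trials following
#' distractor-present trials (the congruency-sequence, or Gratton,
#' effect). The previous trial's status comes from the raw sequence
#' position regardless of whether that trial itself survived
#' filtering. Subjects x blocks with any empty (previous x current)
#' cell get `NA` with reason "empty conditional cell".
#'
#' @param trials A filtered trial table with a `prev_distractor`
#'   column (see [filter_trials()]).
#' @return A tibble with one row per subject x block: `i_after_dis`,
#'   `i_after_no_dis`, `modulation` (ms), the four conditional cell
#'   counts, and `reason`.
#' @export
conflict_modulation <- function(trials) {
  check_trials(trials)
  if (!"prev_distractor" %in% names(trials)) {
    stop("`trials` needs a `prev_distractor` column; run filter_trials().",
         call. = FALSE)
  }
  usable <- trials |> dplyr::filter(!is.na(.data$prev_distractor))
  usable |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(
      n_dis_after_dis = sum(.data$distractor & .data$prev_distractor),
      n_no_dis_after_dis = sum(!.data$distractor & .data$prev_distractor),
      n_dis_after_no_dis = sum(.data$distractor & !.data$prev_distractor),
      n_no_dis_after_no_dis = sum(!.data$distractor & !.data$prev_distractor),
      i_after_dis =
        mean(.data$rt[.data$distractor & .data$prev_distractor]) -
        mean(.data$rt[!.data$distractor & .data$prev_distractor]),
      i_after_no_dis =
        mean(.data$rt[.data$distractor & !.data$prev_distractor]) -
        mean(.data$rt[!.data$distractor & !.data$prev_distractor]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      complete = .data$n_dis_after_dis >= 1L & .data$n_no_dis_after_dis >= 1L &
        .data$n_dis_after_no_dis >= 1L & .data$n_no_dis_after_no_dis >= 1L,
      modulation = dplyr::if_else(
        .data$complete, .data$i_after_no_dis - .data$i_after_dis, NA_real_
      ),
      i_after_dis = dplyr::if_else(.data$complete, .data$i_after_dis,
                                   NA_real_),
      i_after_no_dis = dplyr::if_else(.data$complete, .data$i_after_no_dis,
                                      NA_real_),
      reason = dplyr::if_else(.data$complete, NA_character_,
                              "empty conditional cell")
    ) |>
    dplyr::select(-"complete")
}

#' Per-subject summary of all behavioral measures
#'
#' One-stop summary from a raw trial table: applies [filter_trials()],
#' computes per subject x block interference and conflict-driven
#' modulation from the survivors, and error-rate analogues (error-rate
#' difference between distractor conditions, and its
#' sequence-conditioned modulation) from all non-practice,
#' non-block-initial trials with errors retained.
#'
#' @param trials Raw trial table (see [filter_trials()] for required
#'   columns; group factors `valence`/`arousal` are carried through
#'   when present).
#' @param rt_cutoff Outlier threshold in ms passed to
#'   [filter_trials()]. Default 1400.
#'
#' @return A tibble of class `ca_subject_summary`, one row per
#'   subject x block, with the exclusion log attached as attribute
#'   `"exclusion_log"`.
#' @examples
#' trials <- generate_cohort(generator_config(n_per_group = 4), seed = 1)
#' subject_summaries(trials)
#' @export
subject_summaries <- function(trials, rt_cutoff = 1400) {
  check_trials(trials)
  kept <- filter_trials(trials, rt_cutoff = rt_cutoff)
  int <- interference(kept) |>
    dplyr::rename(reason_interference = "reason")
  mod <- conflict_modulation(kept) |>
    dplyr::rename(reason_modulation = "reason")
  err <- annotate_previous(trials) |>
    dplyr::filter(.data$block > 0, .data$trial > 1) |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::summarise(
      error_rate = mean(.data$error),
      error_interference = mean(.data$error[.data$distractor]) -
        mean(.data$error[!.data$distractor]),
      error_modulation =
        (mean(.data$error[.data$distractor & !.data$prev_distractor]) -
           mean(.data$error[!.data$distractor & !.data$prev_distractor])) -
        (mean(.data$error[.data$distractor & .data$prev_distractor]) -
           mean(.data$error[!.data$distractor & .data$prev_distractor])),
      .groups = "drop"
    )
  groups <- trials |>
    tibble::as_tibble() |>
    dplyr::distinct(dplyr::pick(dplyr::any_of(
      c("subject", "valence", "arousal")
    )))
  out <- groups |>
    dplyr::inner_join(int, by = "subject") |>
    dplyr::left_join(mod, by = c("subject", "block")) |>
    dplyr::left_join(err, by = c("subject", "block")) |>
    dplyr::arrange(.data$subject, .data$block)
  structure(out, exclusion_log = attr(kept, "exclusion_log"),
            class = c("ca_subject_summary", class(out)))
}

#' Subject-level correlation between interference and its modulation
#'
#' Pearson correlation across subjects between interference and
#' conflict-driven modulation within one block, with its two-sided
#' p-value and 95% confidence interval. Subjects missing either
#' measure are dropped; zero variance in either measure yields an
#' undefined (flagged) result rather than an error.
#'
#' @param summaries A [subject_summaries()] table.
#' @param block Which block to correlate within. Default 1.
#' @return A one-row tibble: `block`, `n`, `r`, `conf_low`,
#'   `conf_high`, `p_value`, `undefined`.
#' @export
interference_modulation_correlation <- function(summaries, block = 1) {
  stopifnot(is.data.frame(summaries),
            all(c("subject", "block", "interference", "modulation") %in%
                  names(summaries)))
  b <- block
  use <- summaries |>
    dplyr::filter(.data$block == b, !is.na(.data$interference),
                  !is.na(.data$modulation))
  if (nrow(use) < 3L) {
    stop("Need at least 3 subjects with both measures.", call. = FALSE)
  }
  if (stats::sd(use$interference) == 0 || stats::sd(use$modulation) == 0) {
    warning("Zero variance in a measure; correlation undefined.",
            call. = FALSE)
    return(tibble::tibble(
      block = b, n = nrow(use), r = NA_real_, conf_low = NA_real_,
      conf_high = NA_real_, p_value = NA_real_, undefined = TRUE
    ))
  }
  ct <- stats::cor.test(use$interference, use$modulation)
  tibble::tibble(
    block = b, n = nrow(use), r = unname(ct$estimate),
    conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
    p_value = ct$p.value, undefined = FALSE
  )
}
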