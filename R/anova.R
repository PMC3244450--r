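#' Mixed-design factorial summary of a behavioral measure
#'
#' Fits the study's 2 (valence, between) x 2 (arousal, between) x
#' 2 (block, within) mixed-design ANOVA to a per-subject measure via
#' sums of squares (through [stats::aov()] with an
#' `Error(subject/block)` stratum), and reports F, degrees of freedom,
#' p-values and partial eta-squared (SS_effect / (SS_effect +
#' SS_error)) for every main effect and interaction, cell means with
#' standard errors, and per-block simple main effects (between-subject
#' ANOVA within each block). Subjects missing the measure in any block
#' are dropped listwise with a warning. Sums of squares are
#' sequential; for the balanced designs this targets they coincide
#' with the usual partial tests.
#'
#' @param summaries A [subject_summaries()] table (or any data frame
#'   with `subject`, `valence`, `arousal`, `block` and the measure).
#' @param measure Which column to analyze: `"interference"`,
#'   `"modulation"`, `"error_rate"`, `"error_interference"` or
#'   `"error_modulation"`.
#'
#' @return An object of class `ca_anova`: a list with `measure`,
#'   `effects` (tibble), `cell_means`, `simple_effects`, `n_subjects`,
#'   `n_dropped`. [tidy()] returns the effects table, [glance()] a
#'   one-row overview.
#' @examples
#' trials <- generate_cohort(generator_config(n_per_group = 6), seed = 2)
#' fit <- factorial_summary(subject_summaries(trials), "interference")
#' tidy(fit)
#' @export
factorial_summary <- function(summaries,
                              measure = c("interference", "modulation",
                                          "error_rate", "error_interference",
                                          "error_modulation")) {
  measure <- match.arg(measure)
  need <- c("subject", "valence", "arousal", "block", measure)
  if (!is.data.frame(summaries) || !all(need %in% names(summaries))) {
    stop("`summaries` must have columns ", paste(need, collapse = ", "), ".",
         call. = FALSE)
  }
  dat <- summaries |>
    tibble::as_tibble() |>
    dplyr::select(dplyr::all_of(need)) |>
    dplyr::rename(value = dplyr::all_of(measure))
  incomplete <- dat |>
    dplyr::group_by(.data$subject) |>
    dplyr::filter(anyNA(.data$value) | dplyr::n() < 2L) |>
    dplyr::pull(.data$subject) |>
    unique()
  if (length(incomplete) > 0L) {
    warning(sprintf(
      "Dropping %d subject(s) with missing %s in at least one block.",
      length(incomplete), measure
    ), call. = FALSE)
    dat <- dat |> dplyr::filter(!.data$subject %in% incomplete)
  }
  n_per_cell <- dat |>
    dplyr::filter(.data$block == min(.data$block)) |>
    dplyr::count(.data$valence, .data$arousal)
  if (nrow(n_per_cell) < 4L || any(n_per_cell$n < 2L)) {
    stop("Need at least 2 subjects per valence x arousal group.",
         call. = FALSE)
  }
  dat <- dat |>
    dplyr::mutate(
      subject = factor(.data$subject),
      valence = factor(.data$valence),
      arousal = factor(.data$arousal),
      block = factor(.data$block)
    )
  fit <- stats::aov(
    value ~ valence * arousal * block + Error(subject / block),
    data = dat
  )
  effects <- extract_mixed_effects(fit)
  cell_means <- dat |>
    dplyr::group_by(.data$valence, .data$arousal, .data$block) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  simple_effects <- dat |>
    dplyr::group_by(.data$block) |>
    dplyr::group_modify(function(d, key) {
      sfit <- stats::aov(value ~ valence * arousal, data = d)
      extract_between_effects(sfit)
    }) |>
    dplyr::ungroup()
  structure(
    list(
      measure = measure,
      effects = effects,
      cell_means = cell_means,
      simple_effects = simple_effects,
      n_subjects = dplyr::n_distinct(dat$subject),
      n_dropped = length(incomplete)
    ),
    class = "ca_anova"
  )
}

# Effects table from an aovlist with subject and subject:block strata.
extract_mixed_effects <- function(fit) {
  strata <- summary(fit)
  purrr::map_dfr(names(strata), function(nm) {
    tab <- strata[[nm]][[1]]
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    if (!any(resid)) return(NULL)
    ss_err <- tab[resid, "Sum Sq"]
    df_err <- tab[resid, "Df"]
    tibble::tibble(
      stratum = gsub("^Error: ", "", nm),
      effect = terms[!resid],
      df = tab[!resid, "Df"],
      df_error = df_err,
      sum_sq = tab[!resid, "Sum Sq"],
      statistic = tab[!resid, "F value"],
      p_value = tab[!resid, "Pr(>F)"],
      partial_eta_sq = tab[!resid, "Sum Sq"] /
        (tab[!resid, "Sum Sq"] + ss_err)
    )
  })
}

# Effects table from a plain between-subject aov fit.
extract_between_effects <- function(fit) {
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  resid <- terms == "Residuals"
  ss_err <- tab[resid, "Sum Sq"]
  df_err <- tab[resid, "Df"]
  tibble::tibble(
    effect = terms[!resid],
    df = tab[!resid, "Df"],
    df_error = df_err,
    sum_sq = tab[!resid, "Sum Sq"],
    statistic = tab[!resid, "F value"],
    p_value = tab[!resid, "Pr(>F)"],
    partial_eta_sq = tab[!resid, "Sum Sq"] / (tab[!resid, "Sum Sq"] + ss_err)
  )
}

#' @export
print.ca_anova <- function(x, ...) {
  cat(sprintf("Mixed-design ANOVA of %s (%d subjects", x$measure,
              x$n_subjects))
  if (x$n_dropped > 0) cat(sprintf(", %d dropped", x$n_dropped))
  cat(")\n\n")
  print(as.data.frame(x$effects), digits = 4)
  invisible(x)
}

#' @export
tidy.ca_anova <- function(x, ...) {
  x$effects
}

#' @export
glance.ca_anova <- function(x, ...) {
  tibble::tibble(
    measure = x$measure,
    n_subjects = x$n_subjects,
    n_dropped = x$n_dropped,
    n_effects = nrow(x$effects)
  )
}
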