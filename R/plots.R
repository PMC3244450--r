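#' Diagnostic surfaces for a parameter sweep
#'
#' Tile maps of mean control and mean control adaptation over the
#' (`lambda`, `alpha`) plane, faceted over a few `beta` slices. Mean
#' control should vary with `alpha` (and across facets with `beta`)
#' but be flat in `lambda`; adaptation should increase with both
#' `lambda` and `alpha` and be flat across facets.
#'
#' @param object A `ca_sweep` from [run_sweep()].
#' @param measure `"mean_control"` or `"mean_adaptation"`.
#' @param beta_slices How many `beta` levels to facet over. Default 4.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_sweep <- function(object, measure = c("mean_adaptation",
                                                  "mean_control"),
                              beta_slices = 4, ...) {
  measure <- match.arg(measure)
  betas <- unique(object$beta)
  keep <- betas[unique(round(seq(1, length(betas),
                                 length.out = beta_slices)))]
  dat <- dplyr::filter(object, .data$beta %in% keep)
  ggplot2::ggplot(dat, ggplot2::aes(.data$lambda, .data$alpha,
                                    fill = .data[[measure]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~beta, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c(name = gsub("_", " ", measure)) +
    ggplot2::labs(
      x = expression(lambda~"(control adaptation)"),
      y = expression(alpha~"(conflict gain)")
    ) +
    ggplot2::theme_minimal()
}

#' Group-level interference and modulation means
#'
#' Point-range plot of the per-group means (with standard errors) of
#' interference and conflict-driven modulation by valence, arousal and
#' block, from a [subject_summaries()] table.
#'
#' @param object A `ca_subject_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_subject_summary <- function(object, ...) {
  dat <- object |>
    tidyr::pivot_longer(c("interference", "modulation"),
                        names_to = "measure", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$valence, .data$arousal, .data$block,
                    .data$measure) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$arousal, .data$mean,
                                    colour = .data$valence)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::facet_grid(measure ~ block,
                        labeller = ggplot2::labeller(
                          block = function(b) paste("block", b)
                        )) +
    ggplot2::labs(x = "arousal", y = "ms", colour = "valence") +
    ggplot2::theme_minimal()
}

#' Cell means of a factorial summary
#'
#' @param object A `ca_anova` from [factorial_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ca_anova <- function(object, ...) {
  ggplot2::ggplot(object$cell_means,
                  ggplot2::aes(.data$arousal, .data$mean,
                               colour = .data$valence)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$se,
                   ymax = .data$mean + .data$se),
      position = ggplot2::position_dodge(width = 0.3)
    ) +
    ggplot2::facet_wrap(~block, labeller = ggplot2::label_both) +
    ggplot2::labs(y = object$measure, colour = "valence") +
    ggplot2::theme_minimal()
}
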