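#' Dissociability of two experimental factors
#'
#' Evaluates the three conditions under which two experimental factors
#' have dissociable effects on control and control adaptation:
#' (i) one factor affects interference but not its conflict-driven
#' modulation, (ii) the other factor affects the modulation but not
#' interference, and (iii) interference and modulation are uncorrelated
#' across subjects. "Affects" means a p-value below `alpha`;
#' "no correlation" means the correlation's two-sided p-value is at or
#' above `alpha`. The overall verdict is the conjunction of the three.
#'
#' @param factor_effects Data frame with columns `factor`, `measure`
#'   (values `"interference"` and `"modulation"`) and `p_value`, one
#'   row per factor x measure (exactly two factors).
#' @param r Subject-level Pearson correlation between interference and
#'   modulation.
#' @param r_p_value Two-sided p-value of `r`.
#' @param alpha Decision threshold. Default 0.05.
#'
#' @return An object of class `ca_dissociability`: a list with the
#'   per-condition booleans, the factor-to-role assignment when one
#'   exists, the inputs, and `verdict`.
#' @examples
#' eff <- tibble::tribble(
#'   ~factor,   ~measure,       ~p_value,
#'   "arousal", "interference", 0.004,
#'   "arousal", "modulation",   0.60,
#'   "valence", "interference", 0.70,
#'   "valence", "modulation",   0.024
#' )
#' dissociability_check(eff, r = 0.04, r_p_value = 0.647)
#' @export
dissociability_check <- function(factor_effects, r, r_p_value, alpha = 0.05) {
  need <- c("factor", "measure", "p_value")
  if (!is.data.frame(factor_effects) || !all(need %in% names(factor_effects))) {
    stop("`factor_effects` must have columns factor, measure, p_value.",
         call. = FALSE)
  }
  factors <- unique(factor_effects$factor)
  if (length(factors) != 2L) {
    stop("Exactly two factors are required.", call. = FALSE)
  }
  p_of <- function(f, m) {
    p <- factor_effects$p_value[
      factor_effects$factor == f & factor_effects$measure == m
    ]
    if (length(p) != 1L || is.na(p)) {
      stop(sprintf("Missing p-value for factor '%s' on measure '%s'.", f, m),
           call. = FALSE)
    }
    p
  }
  affects <- function(f, m) p_of(f, m) < alpha
  # role: "interference-only" factor vs "modulation-only" factor
  interference_only <- vapply(
    factors, function(f) affects(f, "interference") && !affects(f, "modulation"),
    logical(1)
  )
  modulation_only <- vapply(
    factors, function(f) affects(f, "modulation") && !affects(f, "interference"),
    logical(1)
  )
  assignment <- NULL
  condition_i <- FALSE
  condition_ii <- FALSE
  for (k in 1:2) {
    other <- 3L - k
    if (interference_only[k] && modulation_only[other]) {
      assignment <- c(interference = factors[k], modulation = factors[other])
      condition_i <- TRUE
      condition_ii <- TRUE
      break
    }
  }
  if (is.null(assignment)) {
    condition_i <- any(interference_only)
    condition_ii <- any(modulation_only)
  }
  if (!is.numeric(r) || !is.numeric(r_p_value) || is.na(r) || is.na(r_p_value)) {
    stop("`r` and `r_p_value` must be non-missing numbers.", call. = FALSE)
  }
  condition_iii <- r_p_value >= alpha
  structure(
    list(
      condition_i = condition_i,
      condition_ii = condition_ii,
      condition_iii = condition_iii,
      verdict = condition_i && condition_ii && condition_iii,
      assignment = assignment,
      factor_effects = tibble::as_tibble(factor_effects),
      r = r,
      r_p_value = r_p_value,
      alpha = alpha
    ),
    class = "ca_dissociability"
  )
}

#' @export
print.ca_dissociability <- function(x, ...) {
  yn <- function(b) if (b) "satisfied" else "NOT satisfied"
  cat("Dissociability of factor effects on adaptive executive control\n")
  if (!is.null(x$assignment)) {
    cat(sprintf(
      "  roles: %s -> interference only, %s -> modulation only\n",
      x$assignment[["interference"]], x$assignment[["modulation"]]
    ))
  }
  cat(sprintf("  (i)   one factor affects interference only: %s\n",
              yn(x$condition_i)))
  cat(sprintf("  (ii)  the other affects modulation only:     %s\n",
              yn(x$condition_ii)))
  cat(sprintf("  (iii) no interference-modulation correlation (r = %.3f, p = %.3f): %s\n",
              x$r, x$r_p_value, yn(x$condition_iii)))
  cat(sprintf("  verdict: %s\n",
              if (x$verdict) "dissociable" else "not dissociable"))
  invisible(x)
}

#' @export
tidy.ca_dissociability <- function(x, ...) {
  tibble::tibble(
    condition = c("i_interference_only_factor", "ii_modulation_only_factor",
                  "iii_no_correlation", "verdict"),
    satisfied = c(x$condition_i, x$condition_ii, x$condition_iii, x$verdict)
  )
}
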