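#' @importFrom rlang .data %||%
#' @importFrom Rcpp sourceCpp
#' @useDynLib conflictadapt, .registration = TRUE
NULL

# One child seed per consumer (cell, replicate, cohort ...), drawn from
# a stream initialized by the master seed. Seeds are indexed by
# position, so results do not depend on evaluation order. All seeds
# stay below 2^31 - 1.
child_seeds <- function(n, master = NULL) {
  if (!is.null(master)) set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
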