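# broom-style accessors for the report object.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the per-conformer rows of an ensemble report
#'
#' @param x An `ensemble_report` from [table1_report()].
#' @param ... Unused.
#' @return The per-conformer flag tibble (one row per windowed
#'   conformer, with Boltzmann `weight`).
#' @exportS3Method generics::tidy
tidy.ensemble_report <- function(x, ...) {
  x$flags
}

#' One-row summary of an ensemble report
#'
#' @param x An `ensemble_report` from [table1_report()].
#' @param ... Unused.
#' @return The one-row summary tibble (counts, global-minimum flags,
#'   Boltzmann fractions, mean d-alpha, designation).
#' @exportS3Method generics::glance
glance.ensemble_report <- function(x, ...) {
  x$summary
}
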