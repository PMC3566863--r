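# NMR evidence for intramolecular hydrogen bonding: amide-proton
# temperature coefficients and DMSO titration shifts, with the standard
# CDCl3-mode interpretation.

#' Amide-proton temperature coefficient
#'
#' Ordinary-least-squares slope of chemical shift (ppm) against
#' temperature (K), scaled to ppb per K. The slope is reported signed;
#' classification ([classify_nh_state()]) uses its magnitude.
#'
#' @param series Data frame with columns `T_K` (strictly increasing) and
#'   `delta_ppm`; at least 3 points.
#' @return Slope in ppb K^-1.
#' @examples
#' s <- make_nmr_series(slope = -7, intercept = 6.78, sigma = 0)
#' temp_coefficient(s)
#' @export
temp_coefficient <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("T_K", "delta_ppm") %in% names(series)))
  if (nrow(series) < 3) {
    stop("need at least 3 points to fit a temperature coefficient",
         call. = FALSE)
  }
  if (any(diff(series$T_K) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  fit <- stats::lm(delta_ppm ~ T_K, data = series)
  unname(stats::coef(fit)[2]) * 1000
}

#' Classify the hydrogen-bonding state of an amide N-H
#'
#' CDCl3-mode convention: in a low-polarity solvent a *large* magnitude
#' of the temperature coefficient (|coef| >= 4 ppb/K) indicates an
#' equilibrium between hydrogen-bonded and free states (the shift moves
#' as the equilibrium shifts with temperature), a *small* magnitude
#' (|coef| <= 3) a uniformly non-hydrogen-bonded proton, and the gap in
#' between is indeterminate. Note this is the opposite convention to
#' DMSO; only the CDCl3 mode is implemented.
#'
#' @param coef Temperature coefficient in ppb K^-1 (signed or absolute).
#' @param solvent Solvent label; must be `"CDCl3"`.
#' @return `"equilibrium_bonded"`, `"non_bonded"` or `"indeterminate"`.
#' @examples
#' classify_nh_state(7.0) # equilibrium_bonded
#' classify_nh_state(2.3) # non_bonded
#' @export
classify_nh_state <- function(coef, solvent = "CDCl3") {
  if (!identical(solvent, "CDCl3")) {
    stop("only the CDCl3 interpretation mode is supported", call. = FALSE)
  }
  a <- abs(coef)
  if (a >= 4) {
    "equilibrium_bonded"
  } else if (a <= 3) {
    "non_bonded"
  } else {
    "indeterminate"
  }
}

#' Chemical-shift change over a DMSO titration
#'
#' delta(max %) - delta(0 %): the response of an N-H shift to adding a
#' competitive hydrogen-bond-accepting cosolvent. Depends only on the
#' endpoints.
#'
#' @param series Data frame with columns `pct_dmso` (first point must be
#'   0) and `delta_ppm`; at least 2 points.
#' @return Signed shift change in ppm (take `abs()` for classification).
#' @export
titration_delta <- function(series) {
  series <- as_tibble(series)
  stopifnot(all(c("pct_dmso", "delta_ppm") %in% names(series)))
  if (nrow(series) < 2) {
    stop("need at least the 0% and the endpoint measurement", call. = FALSE)
  }
  if (series$pct_dmso[1] != 0) {
    stop("titration series must start at 0% DMSO", call. = FALSE)
  }
  i_max <- which.max(series$pct_dmso)
  series$delta_ppm[i_max] - series$delta_ppm[1]
}

#' Classify solvent exposure from a titration delta
#'
#' A proton whose shift barely moves when DMSO is added (|delta| below
#' 0.5 ppm over a 0-30% titration) is shielded from the solvent,
#' consistent with an intramolecular hydrogen bond; a large response
#' marks a solvent-exposed N-H.
#'
#' @param delta Shift change in ppm from [titration_delta()].
#' @return `"shielded"` or `"exposed"`.
#' @examples
#' classify_exposure(0.24) # shielded
#' classify_exposure(0.82) # exposed
#' @export
classify_exposure <- function(delta) {
  if (abs(delta) < 0.5) "shielded" else "exposed"
}

#' Full NMR hydrogen-bond evidence table
#'
#' Convenience wrapper: takes temperature series and/or titration series
#' for any number of protons and returns one verdict row per proton.
#'
#' @param temp_series Data frame with columns `label`, `T_K`,
#'   `delta_ppm`, or `NULL`.
#' @param titr_series Data frame with columns `label`, `pct_dmso`,
#'   `delta_ppm`, or `NULL`.
#' @param solvent Solvent mode for [classify_nh_state()].
#' @return Tibble with columns `label`, `temp_coef_ppb_K`, `nh_state`,
#'   `titration_delta_ppm`, `exposure` (NA where a series is missing).
#' @export
nmr_evidence <- function(temp_series = NULL, titr_series = NULL,
                         solvent = "CDCl3") {
  labels <- unique(c(
    if (!is.null(temp_series)) unique(temp_series$label),
    if (!is.null(titr_series)) unique(titr_series$label)
  ))
  purrr::map_dfr(labels, function(lb) {
    coef <- state <- NA
    if (!is.null(temp_series) && lb %in% temp_series$label) {
      coef <- temp_coefficient(dplyr::filter(temp_series, .data$label == lb))
      state <- classify_nh_state(coef, solvent)
    }
    td <- expo <- NA
    if (!is.null(titr_series) && lb %in% titr_series$label) {
      td <- titration_delta(dplyr::filter(titr_series, .data$label == lb))
      expo <- classify_exposure(td)
    }
    tibble(label = lb, temp_coef_ppb_K = as.numeric(coef),
           nh_state = as.character(state),
           titration_delta_ppm = as.numeric(td),
           exposure = as.character(expo))
  })
}
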