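# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Energy / turn-class view of an ensemble report
#'
#' Relative energy against the d-alpha turn probe for every windowed
#' conformer, coloured by hydrogen-bond class, with the 7-Angstrom probe
#' threshold marked.
#'
#' @param object An `ensemble_report` from [table1_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_report <- function(object, ...) {
  df <- dplyr::mutate(
    object$flags,
    class = dplyr::case_when(
      .data$has_hbond_B ~ "alpha-turn (13-ring)",
      .data$has_hbond_A ~ "gamma-turn (7-ring)",
      TRUE ~ "open"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dalpha, y = .data$rel_energy,
                                   colour = .data$class)) +
    ggplot2::geom_vline(xintercept = 7, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(
      x = expression(d[alpha] ~ "(Å)"),
      y = expression(Delta * E ~ "(kcal/mol)"),
      colour = NULL,
      title = "Conformer ensemble: turn classes and the d-alpha probe"
    ) +
    ggplot2::theme_minimal()
}

#' Ramachandran-style view of per-conformer virtual torsions
#'
#' @param report An `ensemble_report` from [table1_report()].
#' @param residue Pseudo-residue to plot (2, 3 or 4).
#' @param m A [region_map()] whose rectangles are drawn underneath.
#' @return A ggplot object.
#' @export
plot_torsion_map <- function(report, residue = 2, m = region_map()) {
  phi_col <- paste0("phi_", residue)
  psi_col <- paste0("psi_", residue)
  rects <- m$regions
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = rects,
      ggplot2::aes(xmin = .data$phi_min, xmax = .data$phi_max,
                   ymin = .data$psi_min, ymax = .data$psi_max),
      fill = "grey90", colour = "grey70"
    ) +
    ggplot2::geom_text(
      data = rects,
      ggplot2::aes(x = (.data$phi_min + .data$phi_max) / 2,
                   y = (.data$psi_min + .data$psi_max) / 2,
                   label = .data$label),
      colour = "grey55"
    ) +
    ggplot2::geom_point(
      data = report$flags,
      ggplot2::aes(x = .data[[phi_col]], y = .data[[psi_col]],
                   colour = .data$has_hbond_B)
    ) +
    ggplot2::coord_cartesian(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi ~ "(deg)"),
                  y = expression(psi ~ "(deg)"),
                  colour = "13-ring H-bond",
                  title = paste0("Virtual torsions, pseudo-residue ",
                                 residue)) +
    ggplot2::theme_minimal()
}

#' Plot an NMR temperature series with its least-squares fit
#'
#' @param series Data frame with columns `label`, `T_K`, `delta_ppm`.
#' @return A ggplot object; the fitted slopes (ppb/K) appear in the
#'   facet labels.
#' @export
plot_temp_series <- function(series) {
  series <- as_tibble(series)
  coefs <- series |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      tibble(coef = temp_coefficient(d))
    }) |>
    dplyr::ungroup()
  lab <- stats::setNames(
    sprintf("%s (%.1f ppb/K)", coefs$label, coefs$coef), coefs$label
  )
  ggplot2::ggplot(series, ggplot2::aes(x = .data$T_K,
                                       y = .data$delta_ppm)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~label, scales = "free_y",
                        labeller = ggplot2::as_labeller(lab)) +
    ggplot2::labs(x = "T (K)", y = expression(delta ~ "(ppm)"),
                  title = "Amide NH temperature dependence") +
    ggplot2::theme_minimal()
}
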