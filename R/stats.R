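# Boltzmann ensemble statistics and the tabular ensemble turn report.

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.R_KCAL <- 0.0019872

#' Boltzmann weights of an ensemble
#'
#' `w_i = exp(-dE_i / RT) / sum_j exp(-dE_j / RT)` with
#' R = 0.0019872 kcal mol^-1 K^-1. Energies are shifted by their minimum
#' before exponentiation, so absolute energies and relative energies give
#' identical weights.
#'
#' @param rel_energies Numeric vector of (relative) energies, kcal/mol.
#' @param temperature Temperature in K (default 298.15).
#' @return Numeric weights, non-negative, summing to 1.
#' @examples
#' boltzmann_weights(c(0, 1, 2))
#' @export
boltzmann_weights <- function(rel_energies, temperature = 298.15) {
  if (length(rel_energies) == 0) {
    stop("empty energy list", call. = FALSE)
  }
  if (temperature <= 0) {
    stop("temperature must be positive", call. = FALSE)
  }
  if (any(!is.finite(rel_energies))) {
    stop("energies must be finite", call. = FALSE)
  }
  e <- rel_energies - min(rel_energies)
  w <- exp(-e / (.R_KCAL * temperature))
  w / sum(w)
}

#' Boltzmann population of a conformer class
#'
#' @param weights Weights from [boltzmann_weights()].
#' @param members Logical (or 0/1) membership flags, same length.
#' @return The summed weight of the class, in [0, 1].
#' @export
class_fraction <- function(weights, members) {
  if (length(weights) != length(members)) {
    stop("weights and membership flags differ in length", call. = FALSE)
  }
  sum(weights[as.logical(members)])
}

#' Lowest relative energy within a conformer class
#'
#' @param rel_energies Relative energies (kcal/mol) of the ensemble.
#' @param members Logical membership flags, same length.
#' @return Minimum relative energy over the class members.
#' @export
class_min_gap <- function(rel_energies, members) {
  if (length(rel_energies) != length(members)) {
    stop("energies and membership flags differ in length", call. = FALSE)
  }
  members <- as.logical(members)
  if (!any(members)) {
    stop("class is empty: no member carries the flag", call. = FALSE)
  }
  min(rel_energies[members])
}

#' Circular mean of angles in degrees
#'
#' atan2 of the mean sine and cosine, wrapped to (-180, 180]. The right
#' average for torsion angles, which live on a circle.
#'
#' @param angles Numeric vector, degrees.
#' @param weights Optional non-negative weights (default equal).
#' @return The circular mean in degrees.
#' @examples
#' circular_mean(c(170, -170)) # 180
#' @export
circular_mean <- function(angles, weights = NULL) {
  if (length(angles) == 0) {
    stop("empty angle list", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- rep(1, length(angles))
  }
  weights <- weights / sum(weights)
  rad <- angles * pi / 180
  wrap_angle(atan2(sum(weights * sin(rad)), sum(weights * cos(rad))) *
               180 / pi)
}

#' Tabular ensemble turn report
#'
#' Summarizes a windowed ensemble plus its per-conformer turn flags into
#' the quantities of a conformational-analysis table: member counts per
#' geometric criterion (H-bond A, H-bond B, d-alpha probe), whether each
#' criterion holds in the global minimum, Boltzmann class populations at
#' the given temperature, the mean d-alpha over the alpha-turn class
#' (unweighted, with a Boltzmann-weighted variant alongside), circular-
#' mean virtual torsions per pseudo-residue over the alpha-turn class
#' (falling back to all members when the class is empty), the composed
#' [turn_designation()], the Boltzmann-weighted circular-mean central
#' phi/psi of the gamma-turn class with its classic/inverse type, and
#' the lowest relative energy of the alpha-turn class.
#'
#' Class conventions: the *alpha-turn class* is the members with H-bond B
#' (the 13-ring 5->1 contact); the *gamma-turn class* those with H-bond A
#' (the 7-ring 5->3 contact).
#'
#' @param e A (windowed) [conformer_ensemble()].
#' @param flags Per-conformer flags from [analyze_ensemble()], one row
#'   per member of `e` in ensemble order.
#' @param temperature Temperature in K for the Boltzmann analysis.
#' @param m A [region_map()] for the designation.
#' @return An object of class `ensemble_report`: a list with `summary`
#'   (one-row tibble), `flags` (the input flags plus `weight`),
#'   `torsion_means`, `designation`, and the call parameters.
#' @export
table1_report <- function(e, flags, temperature = 298.15, m = region_map()) {
  stopifnot(inherits(e, "conformer_ensemble"))
  if (length(e$conformers) == 0) {
    stop("empty ensemble", call. = FALSE)
  }
  if (nrow(flags) != length(e$conformers)) {
    stop("flags must have one row per ensemble member", call. = FALSE)
  }
  w <- boltzmann_weights(e$rel_energies, temperature)
  flags <- dplyr::mutate(flags, weight = w)
  alpha <- flags$has_hbond_B
  gamma <- flags$has_hbond_A
  tor_basis <- if (any(alpha)) flags[alpha, ] else flags
  tor_means <- purrr::map_dfr(2:4, function(k) {
    tibble(
      residue = k,
      phi = circular_mean(tor_basis[[paste0("phi_", k)]]),
      psi = circular_mean(tor_basis[[paste0("psi_", k)]])
    )
  })
  desig <- turn_designation(as.matrix(tor_means[, c("phi", "psi")]), m)
  # gamma-class torsion averages are Boltzmann-weighted: the reference
  # protocol averages over the low-energy conformers carrying the
  # dominant population, which the weights implement without an
  # arbitrary cumulative cut-off
  if (any(gamma)) {
    gk <- flags[gamma, ]
    gamma_phi <- circular_mean(gk$phi_4, gk$weight)
    gamma_psi <- circular_mean(gk$psi_4, gk$weight)
    gamma_type <- classify_gamma(gamma_phi, gamma_psi)
  } else {
    gamma_phi <- gamma_psi <- NA_real_
    gamma_type <- NA_character_
  }
  summary <- tibble(
    n_window = length(e$conformers),
    n_hbond_A = sum(gamma),
    n_hbond_B = sum(alpha),
    n_dalpha_probe = sum(flags$dalpha_probe),
    globmin_hbond_A = flags$has_hbond_A[1],
    globmin_hbond_B = flags$has_hbond_B[1],
    globmin_dalpha_probe = flags$dalpha_probe[1],
    frac_alpha = class_fraction(w, alpha),
    frac_gamma = class_fraction(w, gamma),
    mean_dalpha_alpha = if (any(alpha)) mean(flags$dalpha[alpha]) else NA_real_,
    wmean_dalpha_alpha = if (any(alpha)) {
      sum(flags$dalpha[alpha] * w[alpha]) / sum(w[alpha])
    } else {
      NA_real_
    },
    min_gap_alpha = if (any(alpha)) {
      class_min_gap(e$rel_energies, alpha)
    } else {
      NA_real_
    },
    designation = as.character(desig),
    gamma_phi = gamma_phi,
    gamma_psi = gamma_psi,
    gamma_type = gamma_type,
    temperature = temperature
  )
  structure(
    list(summary = summary, flags = flags, torsion_means = tor_means,
         designation = desig, temperature = temperature),
    class = "ensemble_report"
  )
}

#' @export
print.ensemble_report <- function(x, ...) {
  s <- x$summary
  cat("<ensemble_report>\n")
  cat("  conformers in window : ", s$n_window, "\n", sep = "")
  cat("  H-bond A (7-ring)    : ", s$n_hbond_A,
      if (s$globmin_hbond_A) " +" else "", "\n", sep = "")
  cat("  H-bond B (13-ring)   : ", s$n_hbond_B,
      if (s$globmin_hbond_B) " +" else "", "\n", sep = "")
  cat("  d-alpha < 7 A        : ", s$n_dalpha_probe,
      if (s$globmin_dalpha_probe) " +" else "", "\n", sep = "")
  cat("  Boltzmann alpha/gamma: ",
      formatC(s$frac_alpha, format = "f", digits = 3), " / ",
      formatC(s$frac_gamma, format = "f", digits = 3),
      "  (T = ", s$temperature, " K)\n", sep = "")
  if (is.finite(s$mean_dalpha_alpha)) {
    cat("  mean d-alpha (alpha) : ",
        formatC(s$mean_dalpha_alpha, format = "f", digits = 2), " A\n",
        sep = "")
  }
  cat("  designation          : ", s$designation, "\n", sep = "")
  if (!is.na(s$gamma_type)) {
    cat("  gamma-turn type      : ", s$gamma_type, "\n", sep = "")
  }
  invisible(x)
}

#' Write an ensemble report as TSV (summary + flags) and JSON
#'
#' @param report An `ensemble_report` from [table1_report()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem, default `"report"`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, stem = "report") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_sum <- file.path(dir, paste0(stem, "_summary.tsv"))
  f_flags <- file.path(dir, paste0(stem, "_flags.tsv"))
  f_json <- file.path(dir, paste0(stem, ".json"))
  utils::write.table(report$summary, f_sum, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(report$flags, f_flags, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, torsion_means = report$torsion_means),
    f_json, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(c(summary = f_sum, flags = f_flags, json = f_json))
}
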