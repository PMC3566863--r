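# phi/psi conformational-region classification and composed turn
# designations (e.g. "B-aL-X"), plus the classic/inverse gamma-turn windows.

#' Conformational-region map
#'
#' An ordered list of labelled phi/psi rectangles; classification returns
#' the first rectangle containing the point (closed lower bounds, open
#' upper bounds, except that an upper bound of exactly 180 is closed so
#' the wrapped domain (-180, 180] is fully covered), with a fallback
#' label `"X"`. The default map contains the helical region A
#' (phi in [-140, -30), psi in [-90, 45)), the bridge/beta region B
#' (phi in [-180, -30), psi in [45, 180]) and the left-handed-helical
#' region aL (phi in [30, 180], psi in [-10, 120)). These rectangles are
#' calibrated stand-ins for the published alpha-turn typology (whose
#' exact boundaries are not reprinted here): substitute your preferred
#' definitions via the `regions` argument or [read_region_map()].
#'
#' @param regions A data frame with columns `label`, `phi_min`,
#'   `phi_max`, `psi_min`, `psi_max` (degrees in [-180, 180]), evaluated
#'   in row order.
#' @param fallback Label returned when no rectangle matches.
#' @return An object of class `region_map`.
#' @export
region_map <- function(regions = NULL, fallback = "X") {
  if (is.null(regions)) {
    regions <- tibble(
      label   = c("A", "B", "aL"),
      phi_min = c(-140, -180, 30),
      phi_max = c(-30, -30, 180),
      psi_min = c(-90, 45, -10),
      psi_max = c(45, 180, 120)
    )
  }
  regions <- as_tibble(regions)
  stopifnot(all(c("label", "phi_min", "phi_max", "psi_min", "psi_max")
                %in% names(regions)))
  rng <- c(regions$phi_min, regions$phi_max, regions$psi_min,
           regions$psi_max)
  if (any(rng < -180 | rng > 180)) {
    stop("region bounds must lie within [-180, 180]", call. = FALSE)
  }
  structure(list(regions = regions, fallback = fallback),
            class = "region_map")
}

#' Read / write a region map as YAML
#' @param path File path.
#' @return [read_region_map()] returns a [region_map()].
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  region_map(
    regions = purrr::map_dfr(y$regions, as_tibble),
    fallback = y$fallback %||% "X"
  )
}

#' @rdname read_region_map
#' @param m A [region_map()].
#' @export
write_region_map <- function(m, path) {
  yaml::write_yaml(
    list(regions = purrr::transpose(as.list(m$regions)),
         fallback = m$fallback),
    path
  )
  invisible(path)
}

.in_interval <- function(x, lo, hi) {
  x >= lo & (x < hi | (hi == 180 & x == 180))
}

#' Classify a phi/psi pair into a conformational region
#'
#' Total: every finite wrapped pair receives exactly one label (first
#' matching rectangle wins, otherwise the fallback).
#'
#' @param phi,psi Angles in degrees, wrapped to (-180, 180].
#' @param m A [region_map()].
#' @return A single region label.
#' @examples
#' classify_region(-81.5, 64.5)  # "B"
#' classify_region(146.3, 36.9)  # "aL"
#' classify_region(120.5, -29.3) # "X"
#' @export
classify_region <- function(phi, psi, m = region_map()) {
  stopifnot(inherits(m, "region_map"))
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  for (i in seq_len(nrow(m$regions))) {
    r <- m$regions[i, ]
    if (.in_interval(phi, r$phi_min, r$phi_max) &&
        .in_interval(psi, r$psi_min, r$psi_max)) {
      return(r$label)
    }
  }
  m$fallback
}

#' Compose a three-residue turn designation
#'
#' Concatenates the region labels of the three central pseudo-residues
#' (2, 3, 4) with `"-"`, e.g. `"B-aL-X"`.
#'
#' @param pairs A 3x2 matrix / data frame of (phi, psi) rows, or a list
#'   of three length-2 vectors, for pseudo-residues 2, 3 and 4.
#' @param m A [region_map()].
#' @return An object of class `turn_designation` (a string).
#' @examples
#' turn_designation(rbind(c(-81.5, 64.5), c(146.3, 36.9), c(120.5, -29.3)))
#' @export
turn_designation <- function(pairs, m = region_map()) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) != 3 || ncol(pairs) != 2) {
    stop("exactly three (phi, psi) pairs are required", call. = FALSE)
  }
  labels <- apply(pairs, 1, function(p) classify_region(p[1], p[2], m))
  structure(paste(labels, collapse = "-"), class = "turn_designation")
}

#' @export
print.turn_designation <- function(x, ...) {
  cat("<turn_designation>", unclass(x), "\n")
  invisible(x)
}

#' Classify a gamma-turn from the central residue's phi/psi
#'
#' Inverse gamma-turns have central phi around -75 and psi around +65
#' degrees; classic gamma-turns are the mirror image. The windows used
#' are phi in [-110, -50) with psi in [40, 110) for inverse, and
#' phi in [50, 110) with psi in [-110, -40) for classic.
#'
#' @param phi,psi Central-residue torsions in degrees (wrapped).
#' @return `"inverse"`, `"classic"` or `"none"`.
#' @examples
#' classify_gamma(-80.1, 79.6) # "inverse"
#' @export
classify_gamma <- function(phi, psi) {
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  if (phi >= -110 && phi < -50 && psi >= 40 && psi < 110) {
    return("inverse")
  }
  if (phi >= 50 && phi < 110 && psi >= -110 && psi < -40) {
    return("classic")
  }
  "none"
}
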