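# Per-conformer turn geometry: intramolecular hydrogen-bond detection with
# ring-size taxonomy, the d-alpha reverse-turn probe, and virtual backbone
# torsions.

#' Geometric criteria for intramolecular hydrogen bonds
#'
#' The defaults (H...acceptor below 2.5 Angstrom and donor-H...acceptor
#' angle of at least 120 degrees) follow common practice for
#' molecular-mechanics geometries. The heavy-atom mode instead accepts a
#' donor...acceptor distance cutoff (default 3.5 Angstrom) for ensembles
#' that lack explicit hydrogen coordinates.
#'
#' @param max_ha_dist Maximum H...acceptor distance, Angstrom.
#' @param min_dha_angle Minimum donor-H...acceptor angle, degrees.
#' @param heavy_atom_mode If `TRUE`, test donor...acceptor distance
#'   against `max_da_dist` and ignore the hydrogen geometry.
#' @param max_da_dist Donor...acceptor cutoff for heavy-atom mode.
#' @param min_ring_size Smallest pseudo-cycle reported (default 5, which
#'   excludes an amide's own trivial H-to-O contact, a 4-ring).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_ha_dist = 2.5, min_dha_angle = 120,
                           heavy_atom_mode = FALSE, max_da_dist = 3.5,
                           min_ring_size = 5L) {
  stopifnot(max_ha_dist > 0, max_da_dist > 0,
            min_dha_angle > 0, min_dha_angle <= 180)
  structure(
    list(max_ha_dist = max_ha_dist, min_dha_angle = min_dha_angle,
         heavy_atom_mode = heavy_atom_mode, max_da_dist = max_da_dist,
         min_ring_size = as.integer(min_ring_size)),
    class = "hbond_criteria"
  )
}

#' Detect intramolecular hydrogen bonds in a conformer
#'
#' Screens every typed donor-hydrogen / acceptor pair (see
#' [hbond_typing()]) that is far enough apart through bonds to close a
#' non-trivial pseudo-cycle, and keeps the pairs meeting the geometric
#' criteria. Each contact is annotated with its [pseudo_ring_size()] and,
#' when a [role_map()] is given, a positional label: `"5->1"` for the
#' donor-to-position-1-acceptor contact (the 13-ring of an alpha-turn),
#' `"5->3"` for donor to position-3 (the 7-ring of a gamma-turn), and
#' `"other"` otherwise.
#'
#' @param c A [conformer()].
#' @param g The parent [molecular_graph()] (explicit hydrogens).
#' @param crit An [hbond_criteria()].
#' @param roles Optional [role_map()] for positional labels.
#' @return A tibble sorted by ring size with columns `donor`, `h`,
#'   `acceptor`, `dist_ha`, `angle_dha`, `ring_size`, `label`. Zero rows
#'   when no contact qualifies.
#' @export
detect_hbonds <- function(c, g, crit = hbond_criteria(), roles = NULL) {
  typing <- hbond_typing(g)
  if (nrow(typing$donors) == 0 || nrow(typing$acceptors) == 0) {
    return(tibble(donor = integer(), h = integer(), acceptor = integer(),
                  dist_ha = numeric(), angle_dha = numeric(),
                  ring_size = integer(), label = character()))
  }
  pairs <- tidyr::crossing(typing$donors, typing$acceptors)
  rows <- purrr::pmap_dfr(pairs, function(donor, h, id, kind) {
    if (id == donor) {
      return(NULL)
    }
    ring <- pseudo_ring_size(g, h, id)
    if (ring < crit$min_ring_size) {
      return(NULL)
    }
    if (crit$heavy_atom_mode) {
      d_da <- measure_distance(c, donor, id)
      if (d_da > crit$max_da_dist) {
        return(NULL)
      }
      dist_ha <- NA_real_
      ang <- NA_real_
    } else {
      dist_ha <- measure_distance(c, h, id)
      if (dist_ha > crit$max_ha_dist) {
        return(NULL)
      }
      ang <- .angle_deg(c$xyz, donor, h, id)
      if (ang < crit$min_dha_angle) {
        return(NULL)
      }
    }
    label <- "other"
    if (!is.null(roles) && h == roles$donor_h) {
      if (id == roles$acceptor_pos1) {
        label <- "5->1"
      } else if (id == roles$acceptor_pos3) {
        label <- "5->3"
      }
    }
    tibble(donor = donor, h = h, acceptor = id, dist_ha = dist_ha,
           angle_dha = ang, ring_size = ring, label = label)
  })
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(donor = integer(), h = integer(), acceptor = integer(),
                  dist_ha = numeric(), angle_dha = numeric(),
                  ring_size = integer(), label = character()))
  }
  dplyr::arrange(rows, .data$ring_size)
}

#' Virtual backbone torsions of a conformer
#'
#' phi(k) is the dihedral C'(k-1), N(k), Calpha(k), C'(k); psi(k) is
#' N(k), Calpha(k), C'(k), N(k+1), measured over the role map's backbone
#' triples for pseudo-residues 2-4 and wrapped to (-180, 180]. For a
#' non-peptidic scaffold these are *virtual* torsions over designated
#' atoms, not perceived peptide bonds.
#'
#' @param c A [conformer()].
#' @param roles A [role_map()] with backbone triples for residues 1-5.
#' @return Tibble with columns `residue` (2, 3, 4), `phi`, `psi` (deg).
#' @export
virtual_torsions <- function(c, roles) {
  stopifnot(inherits(roles, "role_map"))
  purrr::map_dfr(2:4, function(k) {
    this <- roles$backbone[[as.character(k)]]
    prev <- roles$backbone[[as.character(k - 1)]]
    nxt <- roles$backbone[[as.character(k + 1)]]
    if (is.null(this) || anyNA(this)) {
      stop("backbone triple missing for pseudo-residue ", k, call. = FALSE)
    }
    phi <- if (!is.null(prev) && !is.na(prev[["c"]])) {
      dihedral_angle(c$xyz, prev[["c"]], this[["n"]], this[["ca"]],
                     this[["c"]])
    } else {
      NA_real_
    }
    psi <- if (!is.null(nxt) && !is.na(nxt[["n"]])) {
      dihedral_angle(c$xyz, this[["n"]], this[["ca"]], this[["c"]],
                     nxt[["n"]])
    } else {
      NA_real_
    }
    tibble(residue = k, phi = phi, psi = psi)
  })
}

#' Assemble the per-conformer turn flags
#'
#' Combines [detect_hbonds()] (7-ring 5->3 contact = H-bond A, 13-ring
#' 5->1 contact = H-bond B), the d-alpha distance between the Calpha-5
#' and Calpha-1 surrogates with its generic reverse-turn probe
#' (d-alpha strictly below 7 Angstrom), and [virtual_torsions()].
#'
#' @param c A [conformer()].
#' @param g The parent [molecular_graph()].
#' @param crit An [hbond_criteria()].
#' @param roles A [role_map()].
#' @return A one-row tibble with columns `has_hbond_A`, `has_hbond_B`,
#'   `dalpha`, `dalpha_probe`, `phi_2`, `psi_2`, `phi_3`, `psi_3`,
#'   `phi_4`, `psi_4`.
#' @export
flag_turns <- function(c, g, crit = hbond_criteria(), roles) {
  stopifnot(inherits(roles, "role_map"))
  hb <- detect_hbonds(c, g, crit, roles)
  has_a <- any(hb$label == "5->3" & hb$ring_size == 7)
  has_b <- any(hb$label == "5->1" & hb$ring_size == 13)
  dalpha <- measure_distance(c, roles$calpha[1], roles$calpha[5])
  tor <- virtual_torsions(c, roles)
  wide <- stats::setNames(
    c(tor$phi, tor$psi),
    c(paste0("phi_", tor$residue), paste0("psi_", tor$residue))
  )
  dplyr::bind_cols(
    tibble(has_hbond_A = has_a, has_hbond_B = has_b,
           dalpha = dalpha, dalpha_probe = dalpha < 7.0),
    as_tibble(as.list(wide[c("phi_2", "psi_2", "phi_3", "psi_3",
                             "phi_4", "psi_4")]))
  )
}

#' Turn flags for every member of an ensemble
#'
#' @param e A [conformer_ensemble()].
#' @param crit An [hbond_criteria()].
#' @param roles A [role_map()].
#' @return A tibble with one row per conformer: the [flag_turns()]
#'   columns plus `conformer`, `energy` and `rel_energy`.
#' @export
analyze_ensemble <- function(e, roles, crit = hbond_criteria()) {
  stopifnot(inherits(e, "conformer_ensemble"))
  flags <- purrr::imap_dfr(e$conformers, function(cf, i) {
    dplyr::bind_cols(
      tibble(conformer = i, energy = e$energies[i],
             rel_energy = e$rel_energies[i]),
      flag_turns(cf, e$graph, crit, roles)
    )
  })
  flags
}
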