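# Conformer container and core 3D geometry shared by the search driver,
# the turn-geometry module and the synthetic backbone builder.

#' A single conformer: coordinates plus energy
#'
#' @param xyz Numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param energy Energy in kcal/mol on the generating backend's absolute
#'   scale (`NA` if unknown). Only *relative* energies are ever compared.
#' @param converged Logical minimization status.
#' @param source Free-form provenance tag (e.g. start index).
#' @return An object of class `conformer`.
#' @export
conformer <- function(xyz, energy = NA_real_, converged = NA, source = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, is.numeric(xyz))
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, energy = as.numeric(energy),
                 converged = converged, source = source),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat("<conformer> ", nrow(x$xyz), " atoms, E = ",
      formatC(x$energy, format = "f", digits = 3), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Euclidean distance between two atoms of a conformer
#'
#' @param c A [conformer()].
#' @param i,j Atom ids.
#' @return Distance in Angstrom.
#' @examples
#' cf <- conformer(rbind(c(0, 0, 0), c(7, 0, 0)))
#' measure_distance(cf, 1, 2)
#' @export
measure_distance <- function(c, i, j) {
  n <- nrow(c$xyz)
  if (any(c(i, j) < 1) || any(c(i, j) > n)) {
    stop("atom id out of range 1..", n, call. = FALSE)
  }
  sqrt(sum((c$xyz[i, ] - c$xyz[j, ])^2))
}

#' Wrap angles in degrees to (-180, 180]
#' @param x Numeric vector of angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) {
  w <- ((x + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Dihedral angle over four atom positions
#'
#' Signed torsion i-j-k-l in degrees, wrapped to (-180, 180], using the
#' standard atan2 formulation (right-handed, IUPAC sign convention).
#'
#' @param xyz Coordinate matrix (rows = atoms).
#' @param i,j,k,l Atom ids defining the torsion.
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(xyz, i, j, k, l) {
  b0 <- xyz[i, ] - xyz[j, ]
  b1 <- xyz[k, ] - xyz[j, ]
  b2 <- xyz[l, ] - xyz[k, ]
  b1n <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1n) * b1n
  w <- b2 - sum(b2 * b1n) * b1n
  x <- sum(v * w)
  y <- sum(.cross3(b1n, v) * w)
  wrap_angle(atan2(y, x) * 180 / pi)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex `j` (degrees) for atoms i-j-k
#' @noRd
.angle_deg <- function(xyz, i, j, k) {
  v1 <- xyz[i, ] - xyz[j, ]
  v2 <- xyz[k, ] - xyz[j, ]
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# ---- rotatable torsions -----------------------------------------------------

#' Rotatable torsions of a molecular graph
#'
#' Acyclic single bonds between non-terminal heavy atoms, each with one
#' reference heavy atom on either side so the torsion is fully defined.
#' Bonds whose rotation only permutes equivalent hydrogens (methyl-like
#' ends) are excluded by the non-terminal rule. Amide C-N bonds (carbonyl
#' carbon to nitrogen) are flagged so the search can keep them near trans.
#'
#' Two-fold symmetric rotors (phenyl-like rings) are marked with
#' `period = 180`: rotating them by 180 degrees permutes equivalent
#' atoms, so torsion comparisons treat such values modulo 180.
#'
#' @param g A [molecular_graph()].
#' @return Tibble with columns `p`, `a`, `b`, `q` (torsion atom ids),
#'   `amide` (logical) and `period` (360, or 180 for symmetric rotors).
#' @export
rotatable_torsions <- function(g) {
  el <- g$atoms$element
  bridges <- igraph::bridges(g$igraph)
  bridge_ends <- igraph::ends(g$igraph, bridges)
  in_ring <- function(a1, a2) {
    !any(bridge_ends[, 1] == as.character(a1) &
           bridge_ends[, 2] == as.character(a2) |
           bridge_ends[, 1] == as.character(a2) &
             bridge_ends[, 2] == as.character(a1))
  }
  heavy_deg <- function(i) {
    nb <- .neighbors(g, i)
    sum(el[nb] != "H")
  }
  rows <- purrr::pmap_dfr(g$bonds, function(a1, a2, order) {
    if (order != 1 || el[a1] == "H" || el[a2] == "H") {
      return(NULL)
    }
    if (in_ring(a1, a2)) {
      return(NULL)
    }
    if (heavy_deg(a1) < 2 || heavy_deg(a2) < 2) {
      return(NULL)
    }
    amide <- FALSE
    for (pair in list(c(a1, a2), c(a2, a1))) {
      if (el[pair[1]] == "C" && el[pair[2]] == "N" &&
          .is_carbonyl_c(g, pair[1])) {
        amide <- TRUE
      }
    }
    pa <- .neighbors(g, a1)
    pa <- pa[pa != a2 & el[pa] != "H"][1]
    qa <- .neighbors(g, a2)
    qa <- qa[qa != a1 & el[qa] != "H"][1]
    period <- if (.is_phenyl_rotor(g, a1, a2) ||
                    .is_phenyl_rotor(g, a2, a1)) 180 else 360
    tibble(p = pa, a = a1, b = a2, q = qa, amide = amide, period = period)
  })
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble(p = integer(), a = integer(), b = integer(),
                  q = integer(), amide = logical(), period = numeric()))
  }
  rows
}

#' Is the branch on the `b` side of bond a-b a bare phenyl ring?
#' @noRd
.is_phenyl_rotor <- function(g, a, b) {
  el <- g$atoms$element
  branch <- .branch_atoms(g, a, b)
  heavy <- branch[el[branch] != "H"]
  if (length(heavy) != 5 || any(el[c(b, heavy)] != "C")) {
    return(FALSE)
  }
  ring <- c(b, heavy)
  sub <- g$bonds[g$bonds$a1 %in% ring & g$bonds$a2 %in% ring, ]
  # a six-carbon cycle: six internal bonds, every atom of degree 2
  nrow(sub) == 6 && all(table(factor(c(sub$a1, sub$a2), levels = ring)) == 2)
}

#' Atoms on the far side of bond a-b (excluding b itself)
#' @noRd
.branch_atoms <- function(g, a, b) {
  ig2 <- igraph::delete_edges(
    g$igraph, igraph::get_edge_ids(g$igraph, c(as.character(a),
                                               as.character(b)))
  )
  comp <- igraph::components(ig2)
  side <- which(comp$membership ==
                  comp$membership[as.character(b)])
  ids <- as.integer(igraph::V(ig2)$name[side])
  setdiff(ids, b)
}

#' Set a torsion angle on a conformer
#'
#' Rotates the branch on the `b` side of the acyclic bond `a-b` about the
#' bond axis so that the dihedral p-a-b-q becomes `value` degrees.
#'
#' @param c A [conformer()].
#' @param g The parent [molecular_graph()].
#' @param p,a,b,q Torsion atom ids (as in [rotatable_torsions()]).
#' @param value Target dihedral in degrees.
#' @return A new [conformer()] with rotated coordinates (energy dropped).
#' @export
set_torsion <- function(c, g, p, a, b, q, value) {
  cur <- dihedral_angle(c$xyz, p, a, b, q)
  delta <- (value - cur) * pi / 180
  axis <- c$xyz[b, ] - c$xyz[a, ]
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]),
             c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  R <- diag(3) + sin(delta) * K + (1 - cos(delta)) * (K %*% K)
  side <- .branch_atoms(g, a, b)
  xyz <- c$xyz
  xyz[side, ] <- sweep(sweep(xyz[side, , drop = FALSE], 2, xyz[b, ]) %*% t(R),
                       2, xyz[b, ], `+`)
  conformer(xyz, energy = NA_real_, converged = NA, source = c$source)
}

#' Best-fit heavy-atom RMSD between two conformers
#'
#' Superposes with the Kabsch algorithm (via [bio3d::fit.xyz()]-style
#' fitting in [bio3d::rmsd()]) over all non-hydrogen atoms.
#'
#' @param g Parent [molecular_graph()] (supplies the element labels).
#' @param c1,c2 [conformer()] objects.
#' @return RMSD in Angstrom.
#' @export
heavy_rmsd <- function(g, c1, c2) {
  heavy <- which(g$atoms$element != "H")
  a <- as.numeric(t(c1$xyz[heavy, , drop = FALSE]))
  b <- as.numeric(t(c2$xyz[heavy, , drop = FALSE]))
  as.numeric(bio3d::rmsd(a, b, fit = TRUE))
}

#' Maximum circular difference over the rotatable torsions
#' @noRd
.max_torsion_diff <- function(g, torsions, c1, c2) {
  if (nrow(torsions) == 0) {
    return(0)
  }
  d <- purrr::pmap_dbl(
    torsions[, c("p", "a", "b", "q", "period")],
    function(p, a, b, q, period) {
      diff <- abs(wrap_angle(dihedral_angle(c1$xyz, p, a, b, q) -
                               dihedral_angle(c2$xyz, p, a, b, q)))
      if (period == 180) min(diff, 180 - diff) else diff
    }
  )
  max(d)
}

#' Tetrahedral parity at the declared stereocentres
#'
#' Sign of the signed volume spanned by the first three id-ordered
#' neighbours and the fourth (or the centre itself for 3-coordinate
#' centres), per stereocentre. Comparing parities between two
#' conformers of the same graph detects stereocentre inversion, which
#' force-field minimization from a heavily clashed geometry can cause.
#'
#' @param g A [molecular_graph()] with a `stereo` table.
#' @param conf A [conformer()].
#' @return Integer vector of +/-1, one per stereocentre (empty when the
#'   graph declares none).
#' @export
stereo_parity <- function(g, conf) {
  if (is.null(g$stereo) || nrow(g$stereo) == 0) {
    return(integer(0))
  }
  vapply(g$stereo$id, function(i) {
    nb <- sort(.neighbors(g, i))
    if (length(nb) >= 4) {
      ref <- conf$xyz[nb[4], ]
    } else if (length(nb) == 3) {
      ref <- conf$xyz[i, ]
    } else {
      return(NA_integer_)
    }
    v <- rbind(conf$xyz[nb[1], ] - ref,
               conf$xyz[nb[2], ] - ref,
               conf$xyz[nb[3], ] - ref)
    as.integer(sign(det(v)))
  }, integer(1))
}
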