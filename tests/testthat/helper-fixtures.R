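# Shared fixtures, built in code. Expensive ones (anything that calls the
# RDKit worker) are memoised per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, fn(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

fixture_graph <- function(compound = "1a") {
  memo(paste0("graph_", compound), function() {
    load_structure(smiles = thbc_dkp_smiles(compound), seed = 1234)
  })
}

fixture_roles <- function(compound = "1a") {
  memo(paste0("roles_", compound), function() {
    derive_thbc_roles(fixture_graph(compound))
  })
}

# Four-atom chain with one rotatable torsion; arms long enough that
# mirror-image torsions are geometrically distinct at the default
# duplicate tolerance.
toy_chain <- function() {
  g <- molecular_graph(
    atoms = tibble::tibble(id = 1:4, element = "C"),
    bonds = tibble::tibble(a1 = 1:3, a2 = 2:4, order = 1L)
  )
  g$conformers <- list(conformer(rbind(
    c(-1.2, 1.8, 0), c(0, 0, 0), c(2.2, 0, 0), c(3.4, 1.8, 0.01)
  )))
  g
}

# Analytic torsional test potential with three wells.
three_well <- function(theta) {
  th <- theta * pi / 180
  2.0 * (1 + cos(th)) + 0.6 * (1 - cos(3 * th))
}

# Independent oracle: local minima of a 1-torsion potential by dense
# grid scan (1-degree steps, circular neighbours).
grid_scan_minima <- function(potential, step = 1) {
  grid <- seq(-180 + step, 180, by = step)
  e <- vapply(grid, function(t) potential(t), numeric(1))
  n <- length(e)
  lower_next <- e < e[c(2:n, 1)]
  lower_prev <- e < e[c(n, 1:(n - 1))]
  grid[lower_next & lower_prev]
}

# Formamide built by hand: H-C(=O)-NH2 with explicit hydrogens.
formamide_graph <- function() {
  molecular_graph(
    atoms = tibble::tibble(
      id = 1:6, element = c("C", "O", "N", "H", "H", "H")
    ),
    bonds = tibble::tibble(
      a1 = c(1, 1, 1, 3, 3),
      a2 = c(2, 3, 4, 5, 6),
      order = c(2L, 1L, 1L, 1L, 1L)
    )
  )
}

methane_graph <- function() {
  molecular_graph(
    atoms = tibble::tibble(id = 1:5, element = c("C", "H", "H", "H", "H")),
    bonds = tibble::tibble(a1 = 1L, a2 = 2:5, order = 1L)
  )
}

# Element-coloured graph isomorphism (for round-trip checks).
graphs_isomorphic <- function(g1, g2) {
  col <- function(g) as.integer(factor(g$atoms$element,
                                       levels = sort(unique(c(g1$atoms$element,
                                                              g2$atoms$element)))))
  igraph::isomorphic(g1$igraph, g2$igraph, method = "vf2",
                     vertex.color1 = col(g1), vertex.color2 = col(g2))
}

# Random rigid motion applied to a conformer.
random_rigid_motion <- function(cf, seed = 1) {
  withr::with_seed(seed, {
    ang <- stats::runif(3, -pi, pi)
    rx <- rbind(c(1, 0, 0),
                c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    rz <- rbind(c(cos(ang[2]), -sin(ang[2]), 0),
                c(sin(ang[2]), cos(ang[2]), 0),
                c(0, 0, 1))
    shift <- stats::runif(3, -20, 20)
    conformer(sweep(cf$xyz %*% (rx %*% rz), 2, shift, `+`),
              energy = cf$energy, converged = cf$converged)
  })
}
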