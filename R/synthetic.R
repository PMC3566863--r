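# Synthetic inputs: ideal peptide backbones built from internal
# coordinates (the test substrate for turn detection -- the detection
# logic is scaffold-agnostic), random-torsion decoys, labelled energy
# sets, and synthetic NMR series.

# Standard peptide internal coordinates (Engh-Huber-like values).
.BB <- list(
  r_n_ca = 1.458, r_ca_c = 1.525, r_c_n = 1.329, r_c_o = 1.231,
  r_n_h = 1.010,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

#' Place atom d from internal coordinates (NeRF)
#'
#' Returns the position at distance `r` from `c`, with angle b-c-d equal
#' to `theta` and dihedral a-b-c-d equal to `chi` (degrees).
#' @noRd
.nerf_place <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- r * c(-cos(th), sin(th) * cos(ch), sin(th) * sin(ch))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- .cross3(n, bc)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build an ideal peptide backbone from phi/psi torsions
#'
#' Constructs an N residue glycine-like backbone (N, Calpha, C', O per
#' residue, amide H on residues 2..N) by sequential internal-coordinate
#' placement with fixed trans amides (omega = 180). Bond lengths and
#' angles are standard peptide values; the carbonyl O and amide H are
#' placed trans in the amide plane. Recomputing phi/psi from the
#' coordinates reproduces the requested values (round-trip within 0.5
#' degrees), which makes these chains a clean substrate for validating
#' turn detection: all (-63, -42) gives an alpha-helical chain whose
#' residue-5 N-H to residue-1 C=O contact closes a 13-ring, a central
#' (-75, 65) gives an inverse-gamma 7-ring.
#'
#' @param n_res Number of residues (>= 2).
#' @param phi,psi Numeric vectors of torsions in degrees, recycled to
#'   `n_res`. `phi[1]` and `psi[n_res]` do not affect the backbone
#'   proper (no preceding C' / following N) but `psi[n_res]` orients the
#'   final carbonyl O.
#' @param omega Amide torsion, fixed default 180 (trans).
#' @return A [molecular_graph()] with one [conformer()] attached and
#'   atom labels `"N1"`, `"CA1"`, `"C1"`, `"O1"`, `"H2"`, ...
#' @export
build_backbone <- function(n_res, phi, psi, omega = 180) {
  stopifnot(n_res >= 2)
  phi <- rep_len(wrap_angle(phi), n_res)
  psi <- rep_len(wrap_angle(psi), n_res)
  b <- .BB
  # backbone chain N, CA, C per residue (+ a virtual N after the last C)
  pos <- list()
  pos[["N1"]] <- c(0, 0, 0)
  pos[["CA1"]] <- c(b$r_n_ca, 0, 0)
  ang <- b$a_n_ca_c * pi / 180
  pos[["C1"]] <- pos[["CA1"]] + b$r_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res)) {
    Ni <- pos[[paste0("N", i)]]
    CAi <- pos[[paste0("CA", i)]]
    Ci <- pos[[paste0("C", i)]]
    Nn <- .nerf_place(Ni, CAi, Ci, b$r_c_n, b$a_ca_c_n, psi[i])
    pos[[paste0("O", i)]] <- .nerf_place(Ni, CAi, Ci, b$r_c_o, b$a_ca_c_o,
                                         psi[i] + 180)
    if (i == n_res) {
      break
    }
    pos[[paste0("N", i + 1)]] <- Nn
    CAn <- .nerf_place(CAi, Ci, Nn, b$r_n_ca, b$a_c_n_ca, omega)
    pos[[paste0("CA", i + 1)]] <- CAn
    pos[[paste0("C", i + 1)]] <- .nerf_place(Ci, Nn, CAn, b$r_ca_c,
                                             b$a_n_ca_c, phi[i + 1])
  }
  # amide hydrogens: in-plane, bisecting externally (trans to both
  # substituents), on residues 2..n
  for (i in seq(2, n_res)) {
    Ni <- pos[[paste0("N", i)]]
    u1 <- pos[[paste0("C", i - 1)]] - Ni
    u2 <- pos[[paste0("CA", i)]] - Ni
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- u2 / sqrt(sum(u2^2))
    h <- -(u1 + u2)
    pos[[paste0("H", i)]] <- Ni + b$r_n_h * h / sqrt(sum(h^2))
  }
  labels <- names(pos)
  idx <- stats::setNames(seq_along(labels), labels)
  element <- dplyr::case_when(
    grepl("^N", labels) ~ "N",
    grepl("^O", labels) ~ "O",
    grepl("^H", labels) ~ "H",
    TRUE ~ "C"
  )
  bonds <- list()
  add_bond <- function(x, y, o = 1L) {
    bonds[[length(bonds) + 1]] <<- c(idx[[x]], idx[[y]], o)
  }
  for (i in seq_len(n_res)) {
    add_bond(paste0("N", i), paste0("CA", i))
    add_bond(paste0("CA", i), paste0("C", i))
    add_bond(paste0("C", i), paste0("O", i), 2L)
    if (i < n_res) {
      add_bond(paste0("C", i), paste0("N", i + 1))
    }
    if (i >= 2) {
      add_bond(paste0("N", i), paste0("H", i))
    }
  }
  bm <- do.call(rbind, bonds)
  g <- molecular_graph(
    atoms = tibble(id = seq_along(labels), element = element,
                   formal_charge = 0L, label = labels),
    bonds = tibble(a1 = bm[, 1], a2 = bm[, 2], order = bm[, 3])
  )
  g$conformers <- list(conformer(do.call(rbind, pos)))
  g
}

#' Role map of a synthetic 5-residue backbone
#'
#' Maps a [build_backbone()] pentapeptide onto the turn-analysis roles:
#' donor = residue-5 N-H, position-1 acceptor = residue-1 carbonyl O
#' (the 13-ring alpha-turn acceptor), position-3 acceptor = residue-3
#' carbonyl O (the 7-ring acceptor), Calpha surrogates = the five real
#' Calpha atoms.
#'
#' @param g A 5-residue backbone graph from [build_backbone()].
#' @return A validated [role_map()].
#' @export
peptide_role_map <- function(g) {
  lab <- g$atoms$label
  idx <- function(x) {
    i <- which(lab == x)
    if (!length(i)) NA_integer_ else i
  }
  if (!all(c("N5", "H5", "O1", "O3") %in% lab)) {
    stop("expected a 5-residue build_backbone() graph", call. = FALSE)
  }
  role_map(
    donor_n = idx("N5"), donor_h = idx("H5"),
    acceptor_pos1 = idx("O1"), acceptor_pos3 = idx("O3"),
    calpha = purrr::map_int(1:5, function(i) idx(paste0("CA", i))),
    backbone = purrr::map(1:5, function(i) {
      c(idx(paste0("N", i)), idx(paste0("CA", i)), idx(paste0("C", i)))
    }) |> stats::setNames(as.character(1:5)),
    gamma_residue = 4L,
    graph = g
  )
}

#' Random-backbone decoy conformers
#'
#' Pentapeptide backbones with phi/psi drawn uniformly on (-180, 180],
#' deterministic per seed. Decoys rarely close a 13-ring hydrogen bond,
#' which makes them the negative control for turn detection.
#'
#' @param n Number of decoys (>= 1).
#' @param seed Integer seed.
#' @param n_res Residues per backbone (default 5).
#' @return A [molecular_graph()] carrying `n` conformers.
#' @export
make_decoys <- function(n, seed = 1L, n_res = 5L) {
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    confs <- purrr::map(seq_len(n), function(k) {
      g1 <- build_backbone(n_res,
                           phi = stats::runif(n_res, -180, 180),
                           psi = stats::runif(n_res, -180, 180))
      cf <- g1$conformers[[1]]
      cf$source <- k
      cf
    })
    g <- build_backbone(n_res, phi = 180, psi = 180)
    g$conformers <- confs
    g
  })
}

#' Labelled relative-energy set
#'
#' A minimal fixture for the Boltzmann machinery: class labels plus
#' relative energies, one of which must be 0 (the global minimum).
#'
#' @param spec Data frame with columns `class` and `rel_energy`, or a
#'   list of `c(class, rel_energy)` pairs.
#' @return A tibble with columns `class`, `rel_energy`.
#' @export
make_energy_set <- function(spec) {
  if (is.list(spec) && !is.data.frame(spec)) {
    spec <- purrr::map_dfr(spec, function(p) {
      tibble(class = as.character(p[[1]]),
             rel_energy = as.numeric(p[[2]]))
    })
  }
  spec <- as_tibble(spec)
  stopifnot(all(c("class", "rel_energy") %in% names(spec)))
  if (!any(spec$rel_energy == 0)) {
    stop("energy set needs a 0 member (the global minimum)", call. = FALSE)
  }
  spec
}

#' Synthetic amide-proton temperature series
#'
#' delta_i = intercept + slope * (T_i - min(T)) / 1000 + noise, with
#' noise ~ N(0, sigma^2), deterministic per seed. Temperatures are `n`
#' equally spaced points over `t_range`.
#'
#' @param slope Temperature coefficient in ppb K^-1.
#' @param intercept Shift at the lowest temperature, ppm.
#' @param sigma Noise SD in ppm (0 = exact line).
#' @param t_range Temperature range in K, default `c(263, 328)`.
#' @param n Number of points (>= 3).
#' @param seed Integer seed.
#' @param label Proton label column value.
#' @return Tibble with columns `label`, `T_K`, `delta_ppm`.
#' @export
make_nmr_series <- function(slope, intercept, sigma = 0,
                            t_range = c(263, 328), n = 8L, seed = 1L,
                            label = "NH") {
  if (n < 3) {
    stop("need at least 3 points (the fitting minimum)", call. = FALSE)
  }
  if (t_range[2] <= t_range[1]) {
    stop("invalid temperature range", call. = FALSE)
  }
  withr::with_seed(seed, {
    t_k <- seq(t_range[1], t_range[2], length.out = n)
    tibble(
      label = label,
      T_K = t_k,
      delta_ppm = intercept + slope * (t_k - t_k[1]) / 1000 +
        stats::rnorm(n, 0, sigma)
    )
  })
}
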