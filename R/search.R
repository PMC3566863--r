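# Monte-Carlo multiple-minimum (MCMM) conformational search:
# torsion-perturbation starts seeded from a usage-directed low-energy pool,
# each start minimized by the pluggable backend, duplicates merged, and the
# survivors windowed on relative energy.

#' Search configuration
#'
#' @param n_starts Number of minimized starts (default 972).
#' @param window Energy window in kcal/mol for [energy_window()]
#'   (default 6; boundary inclusive).
#' @param dup_tol_torsion Duplicate criterion: two conformers are the same
#'   minimum if *all* rotatable-torsion differences are below this many
#'   degrees (circular), default 20.
#' @param dup_tol_rmsd ... or if their best-fit heavy-atom RMSD is below
#'   this many Angstrom, default 0.5.
#' @param seed Integer random seed; the whole search is reproducible for a
#'   fixed (graph, config, backend) triple.
#' @param batch_size Starts minimized per backend call (batching amortizes
#'   worker start-up; no effect on results beyond RNG draw order).
#' @param pool_top New starts are seeded from a conformer drawn uniformly
#'   from the `pool_top` lowest-energy pool members found so far.
#' @param amide_sd Amide (carbonyl-C to N) torsions are perturbed by a
#'   normal step with this SD in degrees instead of uniformly, keeping
#'   them near trans; default 40.
#' @param jitter_sd Optional Cartesian jitter SD in Angstrom applied to
#'   every atom of a start (0 = off), a cheap way to also perturb ring
#'   puckers.
#' @return A list of class `search_config`.
#' @export
search_config <- function(n_starts = 972L, window = 6.0,
                          dup_tol_torsion = 20, dup_tol_rmsd = 0.5,
                          seed = 1L, batch_size = 36L, pool_top = 8L,
                          amide_sd = 40, jitter_sd = 0) {
  stopifnot(n_starts >= 1, window > 0, dup_tol_torsion > 0,
            dup_tol_rmsd > 0, batch_size >= 1, pool_top >= 1)
  structure(
    list(n_starts = as.integer(n_starts), window = window,
         dup_tol_torsion = dup_tol_torsion, dup_tol_rmsd = dup_tol_rmsd,
         seed = as.integer(seed), batch_size = as.integer(batch_size),
         pool_top = as.integer(pool_top), amide_sd = amide_sd,
         jitter_sd = jitter_sd),
    class = "search_config"
  )
}

#' Read / write a search configuration as YAML
#' @param path File path.
#' @return [read_search_config()] returns a [search_config()].
#' @export
read_search_config <- function(path) {
  do.call(search_config, yaml::read_yaml(path))
}

#' @rdname read_search_config
#' @param cfg A [search_config()].
#' @export
write_search_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# ---- ensemble ---------------------------------------------------------------

#' Construct a conformer ensemble
#'
#' @param g Parent [molecular_graph()].
#' @param conformers List of [conformer()]s with finite energies; stored
#'   sorted ascending by energy.
#' @return Object of class `conformer_ensemble` with fields `graph`,
#'   `conformers`, `energies` and `rel_energies` (Delta-E to the global
#'   minimum, so `rel_energies[1] == 0`).
#' @export
conformer_ensemble <- function(g, conformers) {
  stopifnot(inherits(g, "molecular_graph"), length(conformers) >= 1)
  e <- purrr::map_dbl(conformers, "energy")
  if (any(!is.finite(e))) {
    stop("all ensemble members need finite energies", call. = FALSE)
  }
  ord <- order(e)
  conformers <- conformers[ord]
  e <- e[ord]
  structure(
    list(graph = g, conformers = conformers, energies = e,
         rel_energies = e - e[1]),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat("<conformer_ensemble> ", length(x$conformers), " conformers, ",
      "Delta-E range [0, ",
      formatC(max(x$rel_energies), format = "f", digits = 2),
      "] kcal/mol\n", sep = "")
  invisible(x)
}

#' @export
length.conformer_ensemble <- function(x) length(x$conformers)

#' @exportS3Method tibble::as_tibble
as_tibble.conformer_ensemble <- function(x, ...) {
  tibble(
    conformer = seq_along(x$conformers),
    energy = x$energies,
    rel_energy = x$rel_energies,
    converged = purrr::map_lgl(x$conformers, function(cf) {
      isTRUE(cf$converged)
    })
  )
}

#' Read a multi-record SDF (with `E_kcal_mol` fields) as an ensemble
#'
#' The entry point for ensembles minimized elsewhere: every record becomes
#' one conformer of the first record's graph.
#'
#' @param path SDF file path.
#' @return A [conformer_ensemble()].
#' @export
read_ensemble_sdf <- function(path) {
  g <- load_structure(sdf = path)
  conformer_ensemble(g, g$conformers)
}

#' Write an ensemble to a multi-record SDF file
#' @param e A [conformer_ensemble()].
#' @param file Output path.
#' @export
write_ensemble_sdf <- function(e, file) {
  write_structure(e$graph, file, conformers = e$conformers)
}

# ---- duplicate removal ------------------------------------------------------

.is_duplicate <- function(g, tors, c1, c2, tol_torsion, tol_rmsd) {
  if (nrow(tors) > 0 &&
      .max_torsion_diff(g, tors, c1, c2) < tol_torsion) {
    return(TRUE)
  }
  heavy_rmsd(g, c1, c2) < tol_rmsd
}

#' Remove duplicated minima from a set of conformers
#'
#' Greedy, lowest-energy-first: a conformer is a duplicate of an already
#' kept one if all rotatable-torsion differences are below the torsion
#' tolerance (circular) *or* the best-fit heavy-atom RMSD is below the
#' RMSD tolerance. Idempotent.
#'
#' @param g Parent [molecular_graph()].
#' @param conformers List of [conformer()]s (finite energies).
#' @param dup_tol_torsion,dup_tol_rmsd Tolerances; see [search_config()].
#' @return A [conformer_ensemble()] of the kept representatives.
#' @export
deduplicate <- function(g, conformers, dup_tol_torsion = 20,
                        dup_tol_rmsd = 0.5) {
  e <- conformer_ensemble(g, conformers)
  tors <- rotatable_torsions(g)
  kept <- list()
  for (cf in e$conformers) {
    dup <- FALSE
    for (k in kept) {
      # duplicates of a minimized conformer have near-identical energy;
      # skip the geometric test when energies clearly differ
      if (abs(cf$energy - k$energy) > 1.0) {
        next
      }
      if (.is_duplicate(g, tors, cf, k, dup_tol_torsion, dup_tol_rmsd)) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept <- c(kept, list(cf))
    }
  }
  conformer_ensemble(g, kept)
}

#' Apply a relative-energy window to an ensemble
#'
#' Keeps exactly the members with Delta-E at most `window` kcal/mol above
#' the global minimum (boundary inclusive, so a conformer at exactly the
#' window edge is retained). The global minimum is always kept.
#'
#' @param e A [conformer_ensemble()].
#' @param window Window width in kcal/mol (> 0).
#' @return A [conformer_ensemble()] of the retained members.
#' @export
energy_window <- function(e, window = 6.0) {
  stopifnot(inherits(e, "conformer_ensemble"))
  if (length(e$conformers) == 0) {
    stop("empty ensemble", call. = FALSE)
  }
  if (window <= 0) {
    stop("window must be positive", call. = FALSE)
  }
  keep <- e$rel_energies <= window
  conformer_ensemble(e$graph, e$conformers[keep])
}

# ---- the MCMM driver --------------------------------------------------------

#' Monte-Carlo multiple-minimum conformational search
#'
#' Generates `cfg$n_starts` starting geometries and minimizes each with
#' the backend. The first start is the graph's stored conformer; every
#' subsequent start perturbs a random subset of the rotatable torsions of
#' a parent drawn from the lowest-energy pool members found so far
#' (usage-directed basin hopping). Non-amide torsions are redrawn
#' uniformly on (-180, 180]; amide torsions take a normal step of SD
#' `cfg$amide_sd` about their current value, which keeps trans amides
#' trans. Duplicate minima are merged on the fly with the
#' [deduplicate()] criterion.
#'
#' When the graph declares stereocentres, every minimized conformer is
#' checked against the starting structure with [stereo_parity()] and
#' discarded on mismatch: minimization of a heavily clashed start can
#' silently invert a stereocentre, which would contaminate the ensemble
#' with another diastereomer.
#'
#' The run is deterministic for fixed (graph, config, backend): all
#' randomness flows from `cfg$seed` through an isolated RNG stream.
#'
#' @param g A [molecular_graph()] carrying at least one 3D conformer
#'   (e.g. from [load_structure()] or [build_backbone()]).
#' @param cfg A [search_config()].
#' @param backend An [energy_backend] (default [backend_mmff()]).
#' @return A [conformer_ensemble()] of unique minima (window *not*
#'   applied; see [energy_window()]).
#' @export
mc_search <- function(g, cfg = search_config(), backend = backend_mmff()) {
  stopifnot(inherits(g, "molecular_graph"), inherits(cfg, "search_config"))
  if (length(g$conformers) == 0) {
    stop("graph has no starting conformer to search from", call. = FALSE)
  }
  tors <- rotatable_torsions(g)
  ref_parity <- stereo_parity(g, g$conformers[[1]])
  withr::with_seed(cfg$seed, {
    init <- g$conformers[[1]]
    init$source <- 0L
    pool <- backend$minimize_batch(g, list(init))
    pool_e <- purrr::map_dbl(pool, "energy")
    add_to_pool <- function(cf) {
      dup <- FALSE
      near <- which(abs(pool_e - cf$energy) <= 1.0)
      for (j in near) {
        if (.is_duplicate(g, tors, cf, pool[[j]], cfg$dup_tol_torsion,
                          cfg$dup_tol_rmsd)) {
          dup <- TRUE
          if (cf$energy < pool[[j]]$energy) {
            pool[[j]] <<- cf
            pool_e[j] <<- cf$energy
          }
          break
        }
      }
      if (!dup) {
        pool[[length(pool) + 1]] <<- cf
        pool_e[length(pool_e) + 1] <<- cf$energy
      }
    }
    remaining <- cfg$n_starts - 1L
    start_idx <- 0L
    while (remaining > 0L) {
      nb <- min(cfg$batch_size, remaining)
      batch <- purrr::map(seq_len(nb), function(k) {
        ord <- order(pool_e)
        parent <- pool[[ord[sample.int(min(length(pool), cfg$pool_top), 1)]]]
        cf <- conformer(parent$xyz, source = start_idx + k)
        if (nrow(tors) > 0) {
          n_perturb <- sample.int(nrow(tors), 1)
          for (i in sample.int(nrow(tors), n_perturb)) {
            target <- if (tors$amide[i]) {
              dihedral_angle(cf$xyz, tors$p[i], tors$a[i], tors$b[i],
                             tors$q[i]) + stats::rnorm(1, 0, cfg$amide_sd)
            } else {
              stats::runif(1, -180, 180)
            }
            cf <- set_torsion(cf, g, tors$p[i], tors$a[i], tors$b[i],
                              tors$q[i], wrap_angle(target))
          }
        }
        if (cfg$jitter_sd > 0) {
          cf$xyz <- cf$xyz + matrix(stats::rnorm(length(cf$xyz), 0,
                                                 cfg$jitter_sd),
                                    ncol = 3)
        }
        cf$source <- start_idx + k
        cf
      })
      minimized <- backend$minimize_batch(g, batch)
      for (cf in minimized) {
        if (length(ref_parity) &&
            !identical(stereo_parity(g, cf), ref_parity)) {
          next # stereocentre inverted during minimization: not this compound
        }
        add_to_pool(cf)
      }
      start_idx <- start_idx + nb
      remaining <- remaining - nb
    }
    # the in-run pool merge is a heuristic (replacing a representative
    # can create new duplicate pairs among already-checked members);
    # a final greedy lowest-energy-first pass guarantees a clean set
    deduplicate(g, pool, cfg$dup_tol_torsion, cfg$dup_tol_rmsd)
  })
}
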