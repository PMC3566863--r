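# Energy backends. The conformational-search driver only ever sees this
# interface, so the force field is swappable: production work uses MMFF94
# (RDKit, via the bundled worker script); tests use analytic torsional
# potentials whose minima are known in closed form.

#' Energy-and-minimize backend interface
#'
#' A backend is a list with fields
#' \describe{
#'   \item{`name`}{identifier recorded in run manifests,}
#'   \item{`energy(g, conformer)`}{potential energy in kcal/mol,}
#'   \item{`minimize_batch(g, conformers)`}{list of minimized
#'     [conformer()]s, same length and order, each with `energy` and
#'     `converged` filled in.}
#' }
#' Absolute energy zeros are backend-defined; only differences within one
#' backend are meaningful.
#'
#' @name energy_backend
#' @seealso [backend_mmff()], [backend_torsion()]
NULL

#' MMFF94 molecular-mechanics backend
#'
#' Delegates minimization and energy evaluation to RDKit's MMFF94
#' implementation through the bundled `rdkit_worker.py` script, exchanging
#' batches of conformers as multi-record SDF files. Requires a python
#' interpreter with rdkit on the PATH (or pointed to by the
#' `TURNSCOUT_PYTHON` environment variable).
#'
#' @param max_iters Maximum minimizer iterations per conformer.
#' @return A backend list (see [energy_backend]).
#' @export
backend_mmff <- function(max_iters = 20000L) {
  list(
    name = "mmff94/rdkit",
    energy = function(g, conf) {
      fin <- tempfile("energy-", fileext = ".sdf")
      on.exit(unlink(fin), add = TRUE)
      write_structure(g, fin, conformers = list(conf))
      out <- .run_worker(c("energy", "--in", shQuote(fin)))
      as.numeric(out[1])
    },
    minimize_batch = function(g, confs) {
      fin <- tempfile("min-in-", fileext = ".sdf")
      fout <- tempfile("min-out-", fileext = ".sdf")
      on.exit(unlink(c(fin, fout)), add = TRUE)
      write_structure(g, fin, conformers = confs)
      .run_worker(c("minimize", "--in", shQuote(fin), "--out", shQuote(fout),
                    "--max-iters", as.integer(max_iters)))
      res <- load_structure(sdf = fout)
      if (length(res$conformers) != length(confs)) {
        stop("backend returned ", length(res$conformers),
             " conformers for ", length(confs), " inputs", call. = FALSE)
      }
      purrr::map2(res$conformers, confs, function(new, old) {
        new$source <- old$source
        new
      })
    }
  )
}

#' Analytic torsional-potential backend
#'
#' A test backend whose energy is an arbitrary R function of the
#' molecule's rotatable-torsion vector (degrees, in the row order of
#' [rotatable_torsions()]). Minimization is local optimization over the
#' torsions from the current geometry with [stats::optim()], so the
#' search driver sees the same contract as with a molecular-mechanics
#' backend: distinct starting basins relax to distinct minima.
#'
#' @param potential `function(theta)` mapping a numeric vector of torsion
#'   angles (degrees) to an energy (kcal/mol). Must be periodic in 360.
#' @return A backend list (see [energy_backend]).
#' @export
backend_torsion <- function(potential) {
  theta_of <- function(g, conf, tors) {
    purrr::pmap_dbl(tors[, c("p", "a", "b", "q")], function(p, a, b, q) {
      dihedral_angle(conf$xyz, p, a, b, q)
    })
  }
  list(
    name = "analytic-torsion",
    energy = function(g, conf) {
      potential(theta_of(g, conf, rotatable_torsions(g)))
    },
    minimize_batch = function(g, confs) {
      tors <- rotatable_torsions(g)
      purrr::map(confs, function(conf) {
        th0 <- theta_of(g, conf, tors)
        opt <- stats::optim(th0, potential, method = "L-BFGS-B",
                            control = list(factr = 1, pgtol = 1e-12,
                                           maxit = 1000))
        out <- conf
        for (i in seq_len(nrow(tors))) {
          out <- set_torsion(out, g, tors$p[i], tors$a[i], tors$b[i],
                             tors$q[i], wrap_angle(opt$par[i]))
        }
        conformer(out$xyz, energy = opt$value, converged = TRUE,
                  source = conf$source)
      })
    }
  )
}
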