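# End-to-end orchestration: structure + roles + config in, tabular turn
# report, designation and NMR verdicts out, with a reproducibility
# manifest.

#' Run configuration for the analysis pipeline
#'
#' @param smiles,sdf Structure source (exactly one; `sdf` may be a
#'   pre-computed multi-conformer ensemble, in which case the search is
#'   skipped and the records are deduplicated/windowed directly).
#' @param roles A [role_map()], a YAML path, or `NULL` to derive the
#'   THBC-DKP roles automatically via [derive_thbc_roles()].
#' @param search A [search_config()] or YAML path.
#' @param criteria An [hbond_criteria()].
#' @param regions A [region_map()] or YAML path.
#' @param temperature Boltzmann temperature in K.
#' @param backend An [energy_backend] or `NULL` for [backend_mmff()].
#' @param skip_search If `TRUE`, treat the input conformers as already
#'   minimized (deduplicate + window only).
#' @param temp_series,titr_series Optional NMR inputs (data frames or
#'   CSV paths with the [nmr_evidence()] columns).
#' @param out_dir Output directory, or `NULL` to write nothing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(smiles = NULL, sdf = NULL, roles = NULL,
                       search = search_config(),
                       criteria = hbond_criteria(),
                       regions = region_map(), temperature = 298.15,
                       backend = NULL, skip_search = FALSE,
                       temp_series = NULL, titr_series = NULL,
                       out_dir = NULL) {
  if (is.null(smiles) == is.null(sdf)) {
    stop("config needs exactly one structure source (`smiles` or `sdf`)",
         call. = FALSE)
  }
  if (!is.null(sdf) && !file.exists(sdf)) {
    stop("structure file does not exist: ", sdf, call. = FALSE)
  }
  if (is.character(roles)) {
    if (!file.exists(roles)) {
      stop("role-map file does not exist: ", roles, call. = FALSE)
    }
    roles <- read_role_map(roles)
  }
  if (is.character(search)) {
    search <- read_search_config(search)
  }
  if (is.character(regions)) {
    regions <- read_region_map(regions)
  }
  read_tab <- function(x) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop("NMR input file does not exist: ", x, call. = FALSE)
      }
      return(as_tibble(utils::read.csv(x)))
    }
    x
  }
  structure(
    list(smiles = smiles, sdf = sdf, roles = roles, search = search,
         criteria = criteria, regions = regions,
         temperature = temperature, backend = backend,
         skip_search = skip_search,
         temp_series = read_tab(temp_series),
         titr_series = read_tab(titr_series), out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full turn-analysis pipeline
#'
#' Loads the structure, resolves the role map, generates (or ingests)
#' the conformer ensemble, deduplicates and windows it, computes
#' per-conformer turn flags, assembles the [table1_report()], evaluates
#' any NMR series, and optionally writes the whole bundle (ensemble SDF,
#' flags TSV, report TSV/JSON, NMR verdicts JSON, and a manifest
#' recording the seed, backend and a config hash) to `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return A list of class `pipeline_result` with fields `ensemble`
#'   (windowed), `full_ensemble`, `report`, `nmr`, `roles` and
#'   `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- if (!is.null(cfg$smiles)) {
    load_structure(smiles = cfg$smiles, seed = cfg$search$seed)
  } else {
    load_structure(sdf = cfg$sdf)
  }
  roles <- cfg$roles
  if (is.null(roles)) {
    roles <- derive_thbc_roles(g)
  }
  validate_role_map(roles, g)
  backend <- cfg$backend
  if (is.null(backend)) {
    backend <- backend_mmff()
  }
  if (cfg$skip_search) {
    if (any(!is.finite(purrr::map_dbl(g$conformers, "energy")))) {
      stop("skip_search needs records with E_kcal_mol energies",
           call. = FALSE)
    }
    full <- deduplicate(g, g$conformers,
                        cfg$search$dup_tol_torsion,
                        cfg$search$dup_tol_rmsd)
  } else {
    full <- mc_search(g, cfg$search, backend)
  }
  windowed <- energy_window(full, cfg$search$window)
  flags <- analyze_ensemble(windowed, roles, cfg$criteria)
  report <- table1_report(windowed, flags, cfg$temperature, cfg$regions)
  nmr <- NULL
  if (!is.null(cfg$temp_series) || !is.null(cfg$titr_series)) {
    nmr <- nmr_evidence(cfg$temp_series, cfg$titr_series)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("turnscout")),
    backend = backend$name,
    seed = cfg$search$seed,
    n_starts = cfg$search$n_starts,
    window_kcal_mol = cfg$search$window,
    temperature_K = cfg$temperature,
    skip_search = cfg$skip_search,
    n_unique_minima = length(full),
    n_window = length(windowed)
  )
  res <- structure(
    list(ensemble = windowed, full_ensemble = full, report = report,
         nmr = nmr, roles = roles, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ensemble_sdf(windowed, file.path(cfg$out_dir, "ensemble.sdf"))
    write_report(report, cfg$out_dir)
    if (!is.null(nmr)) {
      jsonlite::write_json(nmr, file.path(cfg$out_dir, "nmr_verdicts.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
    cfg_file <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(
      list(smiles = cfg$smiles, sdf = cfg$sdf,
           search = unclass(cfg$search),
           criteria = unclass(cfg$criteria),
           temperature = cfg$temperature),
      cfg_file, auto_unbox = TRUE, digits = NA, na = "null"
    )
    manifest$config_md5 <- unname(tools::md5sum(cfg_file))
    res$manifest <- manifest
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", length(x$full_ensemble), " unique minima, ",
      length(x$ensemble), " in window\n", sep = "")
  print(x$report)
  if (!is.null(x$nmr)) {
    cat("NMR evidence:\n")
    print(x$nmr)
  }
  invisible(x)
}
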