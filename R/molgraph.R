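#' @importFrom rlang %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# ---- python worker plumbing -------------------------------------------------

.python_bin <- function() {
  override <- Sys.getenv("TURNSCOUT_PYTHON", "")
  if (nzchar(override)) {
    return(override)
  }
  for (cand in c("python", "python3")) {
    hit <- Sys.which(cand)
    if (nzchar(hit)) {
      return(unname(hit))
    }
  }
  stop("no python interpreter found; the MMFF backend needs python + rdkit ",
       "(set TURNSCOUT_PYTHON to override)", call. = FALSE)
}

.worker_script <- function() {
  system.file("python", "rdkit_worker.py", package = "turnscout",
              mustWork = TRUE)
}

#' Run the RDKit worker, propagating its diagnostics on failure
#' @noRd
.run_worker <- function(args) {
  errfile <- tempfile("worker-err-")
  on.exit(unlink(errfile), add = TRUE)
  out <- suppressWarnings(
    system2(.python_bin(), c(shQuote(.worker_script()), args),
            stdout = TRUE, stderr = errfile)
  )
  status <- attr(out, "status") %||% 0L
  if (status != 0L) {
    msg <- paste(readLines(errfile, warn = FALSE), collapse = "\n")
    stop("rdkit worker failed (exit ", status, "): ", msg, call. = FALSE)
  }
  out
}

.has_mmff_backend <- function() {
  ok <- tryCatch(nzchar(.python_bin()), error = function(e) FALSE)
  if (!ok) {
    return(FALSE)
  }
  code <- suppressWarnings(
    system2(.python_bin(), c("-c", shQuote("import rdkit")),
            stdout = FALSE, stderr = FALSE)
  )
  identical(code, 0L)
}

# ---- molecular graph --------------------------------------------------------

#' Construct a molecular graph
#'
#' The central container for topology: an atom table, a bond table, optional
#' stereo descriptors, and an [igraph] view used for shortest-path queries.
#' Hydrogens relevant to hydrogen bonding are explicit atoms. Most users will
#' not call this directly but get one from [load_structure()] or
#' [build_backbone()].
#'
#' @param atoms Data frame with columns `id` (1..n integers), `element`
#'   (symbol), and optionally `formal_charge` and `label`.
#' @param bonds Data frame with columns `a1`, `a2` (atom ids) and `order`
#'   (1, 2, 3).
#' @param stereo Optional data frame with columns `id`, `descriptor`
#'   (`"R"`/`"S"`), each attached to an existing atom.
#' @param smiles Optional SMILES string the graph was derived from.
#' @param sdf_lines Optional character vector holding the V2000 record the
#'   graph was parsed from; kept as the template for writing conformers.
#' @return An object of class `molecular_graph`.
#' @export
molecular_graph <- function(atoms, bonds, stereo = NULL, smiles = NULL,
                            sdf_lines = NULL) {
  atoms <- as_tibble(atoms)
  bonds <- as_tibble(bonds)
  stopifnot(all(c("id", "element") %in% names(atoms)),
            all(c("a1", "a2", "order") %in% names(bonds)))
  if (!"formal_charge" %in% names(atoms)) {
    atoms$formal_charge <- 0L
  }
  if (!"label" %in% names(atoms)) {
    atoms$label <- NA_character_
  }
  if (!identical(atoms$id, seq_len(nrow(atoms)))) {
    stop("atom ids must be 1..n in order", call. = FALSE)
  }
  bad <- setdiff(c(bonds$a1, bonds$a2), atoms$id)
  if (length(bad)) {
    stop("bond references unknown atom id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(stereo)) {
    stereo <- as_tibble(stereo)
    if (!all(stereo$id %in% atoms$id)) {
      stop("stereo descriptor attached to a non-existent atom", call. = FALSE)
    }
  }
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = bonds$a1, to = bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = atoms$id)
  )
  structure(
    list(atoms = atoms, bonds = bonds, stereo = stereo, smiles = smiles,
         sdf_lines = sdf_lines, igraph = ig, conformers = list()),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  nh <- sum(x$atoms$element == "H")
  cat("<molecular_graph> ", hill_formula(graph_composition(x)), ": ",
      nrow(x$atoms), " atoms (", nh, " H), ", nrow(x$bonds), " bonds",
      sep = "")
  if (!is.null(x$stereo) && nrow(x$stereo)) {
    cat(", stereocenters ",
        paste0(x$stereo$id, x$stereo$descriptor, collapse = ","), sep = "")
  }
  if (length(x$conformers)) {
    cat(", ", length(x$conformers), " conformer(s)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Element composition of a molecular graph
#'
#' @param g A [molecular_graph()].
#' @return A `composition` (named integer counts), comparable with
#'   [parse_formula()] output and usable with [monoisotopic_mass()].
#' @export
graph_composition <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  tab <- table(g$atoms$element)
  out <- as.integer(tab)
  names(out) <- names(tab)
  # reuse Hill ordering for stable comparisons
  ord <- if ("C" %in% names(out)) {
    c(intersect(c("C", "H"), names(out)),
      sort(setdiff(names(out), c("C", "H"))))
  } else {
    sort(names(out))
  }
  structure(out[ord], class = "composition")
}

# ---- SDF parsing (via ChemmineR) -------------------------------------------

#' Split a multi-record SDF file into per-record line vectors
#' @noRd
.sdf_record_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) {
    ends <- length(lines)
  }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  purrr::map2(starts, ends, function(s, e) lines[s:e])
}

#' Parse one SDFset record into graph pieces
#' @noRd
.graph_from_sdf_record <- function(sdf, record_lines) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  atoms <- tibble(
    id = seq_along(elements),
    element = elements,
    formal_charge = 0L
  )
  bonds <- tibble(
    a1 = as.integer(bb[, 1]),
    a2 = as.integer(bb[, 2]),
    order = as.integer(bb[, 3])
  )
  props <- ChemmineR::datablock(sdf)
  # normalize property names: some writers append a record suffix,
  # e.g. "E_kcal_mol  (1) "
  names(props) <- trimws(sub("\\([0-9]+\\)\\s*$", "", names(props)))
  stereo <- NULL
  if ("stereo_descriptors" %in% names(props) &&
      nzchar(props[["stereo_descriptors"]])) {
    parts <- strsplit(strsplit(props[["stereo_descriptors"]], " ")[[1]], ":")
    stereo <- tibble(
      id = as.integer(purrr::map_chr(parts, 1)),
      descriptor = purrr::map_chr(parts, 2)
    )
  }
  g <- molecular_graph(atoms, bonds, stereo = stereo,
                       sdf_lines = record_lines)
  xyz <- unname(ab[, 1:3, drop = FALSE])
  energy <- if ("E_kcal_mol" %in% names(props)) {
    as.numeric(props[["E_kcal_mol"]])
  } else {
    NA_real_
  }
  converged <- if ("converged" %in% names(props)) {
    as.integer(props[["converged"]]) == 1L
  } else {
    NA
  }
  g$conformers <- list(conformer(xyz, energy = energy, converged = converged))
  g
}

#' Load a molecular structure as a graph (plus any conformers)
#'
#' Reads either a SMILES string (parsed by RDKit through the bundled worker,
#' which also materializes explicit hydrogens, embeds one 3D conformer with
#' ETKDG distance geometry and MMFF94-minimizes it) or an SDF/MOL V2000 file
#' (parsed with ChemmineR; every record becomes a conformer of the first
#' record's graph).
#'
#' @param smiles A SMILES string, or `NULL`.
#' @param sdf Path to an SDF/MOL file, or `NULL`. Exactly one of `smiles`
#'   and `sdf` must be given.
#' @param seed Integer seed for the embedding (SMILES input only).
#' @return A [molecular_graph()] whose `conformers` field holds one
#'   [conformer()] per SDF record (one, for SMILES input). Stereo
#'   descriptors are CIP labels perceived from the embedded 3D structure
#'   for SMILES input, or read from the `stereo_descriptors` SD field
#'   if present.
#' @examples
#' \dontrun{
#' g <- load_structure(smiles = thbc_dkp_smiles("1a"))
#' graph_composition(g)
#' }
#' @export
load_structure <- function(smiles = NULL, sdf = NULL, seed = 1234L) {
  if (is.null(smiles) == is.null(sdf)) {
    stop("give exactly one of `smiles` or `sdf`", call. = FALSE)
  }
  if (!is.null(smiles)) {
    out <- tempfile("prepare-", fileext = ".sdf")
    on.exit(unlink(out), add = TRUE)
    .run_worker(c("prepare", "--smiles", shQuote(smiles),
                  "--seed", as.integer(seed), "--out", shQuote(out)))
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(out))
    g <- .graph_from_sdf_record(sdfset[[1]], .sdf_record_lines(out)[[1]])
    g$smiles <- smiles
    return(g)
  }
  if (!file.exists(sdf)) {
    stop("no such file: ", sdf, call. = FALSE)
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdf))
  recs <- .sdf_record_lines(sdf)
  g <- .graph_from_sdf_record(sdfset[[1]], recs[[1]])
  if (length(sdfset) > 1) {
    extra <- purrr::map(seq(2, length(sdfset)), function(i) {
      gi <- .graph_from_sdf_record(sdfset[[i]], recs[[i]])
      if (nrow(gi$atoms) != nrow(g$atoms)) {
        stop("SDF records have differing atom counts; not one molecule",
             call. = FALSE)
      }
      gi$conformers[[1]]
    })
    g$conformers <- c(g$conformers, extra)
  }
  g
}

# ---- SDF / XYZ writing ------------------------------------------------------

#' Render one V2000 record for a conformer, based on the stored template
#' @noRd
.render_sdf_record <- function(g, conf, title = "turnscout") {
  n <- nrow(g$atoms)
  if (is.null(g$sdf_lines)) {
    # graph built in code (e.g. a synthetic backbone): emit a minimal V2000
    hdr <- c(title, "  turnscout", "",
             sprintf("%3d%3d  0  0  1  0  0  0  0  0999 V2000",
                     n, nrow(g$bonds)))
    atom_lines <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          conf$xyz[, 1], conf$xyz[, 2], conf$xyz[, 3],
                          g$atoms$element)
    bond_lines <- sprintf("%3d%3d%3d  0  0  0  0",
                          g$bonds$a1, g$bonds$a2, g$bonds$order)
    body <- c(hdr, atom_lines, bond_lines, "M  END")
  } else {
    body <- g$sdf_lines
    mend <- grep("^M  END", body)[1]
    body <- body[seq_len(mend)]
    atom_rows <- 4 + seq_len(n)
    body[atom_rows] <- paste0(
      sprintf("%10.4f%10.4f%10.4f", conf$xyz[, 1], conf$xyz[, 2],
              conf$xyz[, 3]),
      substring(body[atom_rows], 31)
    )
  }
  props <- character(0)
  if (is.finite(conf$energy %||% NA_real_)) {
    props <- c(props, ">  <E_kcal_mol>", format(conf$energy, digits = 17), "")
  }
  if (!is.null(conf$converged) && !is.na(conf$converged)) {
    props <- c(props, ">  <converged>", as.character(as.integer(conf$converged)), "")
  }
  if (!is.null(g$stereo) && nrow(g$stereo %||% tibble())) {
    props <- c(props, ">  <stereo_descriptors>",
               paste0(g$stereo$id, ":", g$stereo$descriptor, collapse = " "),
               "")
  }
  c(body, props, "$$$$")
}

#' Write conformers to a multi-record SDF (or multi-frame XYZ) file
#'
#' Each record carries the conformer energy in an `E_kcal_mol` data field,
#' the convention read back by [load_structure()] and [read_ensemble_sdf()].
#'
#' @param g A [molecular_graph()].
#' @param conformers List of [conformer()] objects; defaults to
#'   `g$conformers`.
#' @param file Output path.
#' @param format `"sdf"` (default) or `"xyz"`.
#' @return `file`, invisibly.
#' @export
write_structure <- function(g, file, conformers = g$conformers,
                            format = c("sdf", "xyz")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "molecular_graph"), length(conformers) > 0)
  if (format == "sdf") {
    lines <- unlist(purrr::map(conformers, function(cf) {
      .render_sdf_record(g, cf)
    }))
  } else {
    lines <- unlist(purrr::map(conformers, function(cf) {
      c(nrow(g$atoms),
        sprintf("E_kcal_mol=%s", format(cf$energy %||% NA_real_, digits = 17)),
        sprintf("%-3s %14.8f %14.8f %14.8f", g$atoms$element,
                cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3]))
    }))
  }
  writeLines(lines, file)
  invisible(file)
}

# ---- hydrogen-bond atom typing ---------------------------------------------

.neighbors <- function(g, i) {
  with(g$bonds, c(a2[a1 == i], a1[a2 == i]))
}

.is_carbonyl_c <- function(g, i) {
  if (g$atoms$element[i] != "C") {
    return(FALSE)
  }
  nb <- g$bonds[g$bonds$a1 == i | g$bonds$a2 == i, ]
  any(nb$order == 2 &
        g$atoms$element[ifelse(nb$a1 == i, nb$a2, nb$a1)] == "O")
}

#' Type hydrogen-bond donors and acceptors on a molecular graph
#'
#' Donors are N-H and O-H pairs (one row per hydrogen). Acceptors are
#' oxygens of any kind (carbonyl, carbamate, ester, ether, hydroxyl) plus
#' basic nitrogens, i.e. N with no attached H, only single bonds, and no
#' carbonyl-carbon neighbour (which excludes amide and carbamate N).
#'
#' @param g A [molecular_graph()] with explicit hydrogens on heteroatoms.
#' @return A list with tibbles `donors` (`donor`, `h` atom ids) and
#'   `acceptors` (`id`, `kind`; kind is `"carbonyl_O"`, `"other_O"` or
#'   `"basic_N"`). Both may have zero rows.
#' @export
hbond_typing <- function(g) {
  stopifnot(inherits(g, "molecular_graph"))
  el <- g$atoms$element
  donors <- purrr::map_dfr(which(el %in% c("N", "O")), function(i) {
    hs <- .neighbors(g, i)
    hs <- hs[el[hs] == "H"]
    if (!length(hs)) {
      return(NULL)
    }
    tibble(donor = i, h = hs)
  })
  if (nrow(donors) == 0) {
    donors <- tibble(donor = integer(), h = integer())
  }
  acceptors <- purrr::map_dfr(seq_along(el), function(i) {
    if (el[i] == "O") {
      nb <- g$bonds[g$bonds$a1 == i | g$bonds$a2 == i, ]
      kind <- if (any(nb$order == 2)) "carbonyl_O" else "other_O"
      return(tibble(id = i, kind = kind))
    }
    if (el[i] == "N") {
      nb_ids <- .neighbors(g, i)
      if (any(el[nb_ids] == "H")) {
        return(NULL)
      }
      nb <- g$bonds[g$bonds$a1 == i | g$bonds$a2 == i, ]
      if (any(nb$order > 1)) {
        return(NULL)
      }
      if (any(purrr::map_lgl(nb_ids, function(j) .is_carbonyl_c(g, j)))) {
        return(NULL)
      }
      return(tibble(id = i, kind = "basic_N"))
    }
    NULL
  })
  if (nrow(acceptors) == 0) {
    acceptors <- tibble(id = integer(), kind = character())
  }
  list(donors = donors, acceptors = acceptors)
}

#' Pseudo-cycle ring size closed by an H...acceptor contact
#'
#' The number of atoms in the ring that would be closed by the hydrogen
#' bond: the atoms on the shortest covalent path from the donor hydrogen to
#' the acceptor, inclusive of both endpoints. This counting convention
#' yields the conventional C7 (gamma-turn) and C13 (alpha-turn) labels.
#' Ties between equal-length paths (e.g. the two sides of a diketopiperazine
#' ring) do not affect the returned size.
#'
#' @param g A [molecular_graph()].
#' @param donor_h Atom id of the donor hydrogen.
#' @param acceptor Atom id of the acceptor atom.
#' @return Integer ring size (>= 3 for any pair at least 2 bonds apart;
#'   4 for an amide's own H to its carbonyl O).
#' @export
pseudo_ring_size <- function(g, donor_h, acceptor) {
  stopifnot(inherits(g, "molecular_graph"))
  if (g$atoms$element[donor_h] != "H") {
    stop("donor_h (atom ", donor_h, ") is not a hydrogen", call. = FALSE)
  }
  d <- igraph::distances(g$igraph,
                         v = as.character(donor_h),
                         to = as.character(acceptor))[1, 1]
  if (!is.finite(d)) {
    stop("donor and acceptor are in different connected components",
         call. = FALSE)
  }
  as.integer(d + 1)
}
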