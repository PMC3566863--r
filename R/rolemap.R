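# Pseudo-residue role map: which atoms of a scaffold play the parts of the
# five positions of an alpha-turn (donor N5-H, acceptor carbonyls at
# positions 1 and 3, Calpha surrogates, and the virtual phi/psi triples).

#' Construct a pseudo-residue role map
#'
#' A role map assigns scaffold atoms to the five positions of a reverse
#' turn: the hydrogen-bond donor (the position-5 amide N-H), the acceptor
#' carbonyl oxygens at positions 1 and 3, five Calpha surrogates (position
#' 1 may be a non-carbon surrogate such as the benzyl oxygen of a Cbz
#' group), and the (N, Calpha, C') backbone triple of each pseudo-residue
#' used to measure virtual phi/psi torsions. The backbone of a
#' non-peptidic scaffold cannot be inferred reliably, so the triples are
#' explicit data, not perception.
#'
#' @param donor_n,donor_h Atom ids of the donor nitrogen and its hydrogen.
#' @param acceptor_pos1 Atom id of the position-1 carbonyl oxygen (the
#'   13-ring / alpha-turn acceptor).
#' @param acceptor_pos3 Atom id of the position-3 carbonyl oxygen (the
#'   7-ring / gamma-turn acceptor).
#' @param calpha Integer vector of the five Calpha-surrogate atom ids,
#'   position 1 first.
#' @param backbone A list of up to five `c(n =, ca =, c =)` integer
#'   triples, named `"1"` ... `"5"`; entries may contain `NA` where the
#'   chain terminates (position 1 has no N, position 5 no C').
#' @param gamma_residue Which pseudo-residue is enclosed by the 7-membered
#'   ring and therefore carries the gamma-turn phi/psi (default 4, the
#'   residue between the position-3 carbonyl and the position-5 N-H).
#' @param graph Optional [molecular_graph()] to validate against.
#' @return An object of class `role_map`.
#' @seealso [derive_thbc_roles()] for the shipped THBC-DKP scaffold rules,
#'   [read_role_map()] / [write_role_map()] for YAML persistence.
#' @export
role_map <- function(donor_n, donor_h, acceptor_pos1, acceptor_pos3,
                     calpha, backbone, gamma_residue = 4L, graph = NULL) {
  calpha <- as.integer(calpha)
  stopifnot(length(calpha) == 5)
  if (anyDuplicated(calpha)) {
    stop("the five Calpha surrogates must be distinct atoms", call. = FALSE)
  }
  backbone <- purrr::map(backbone, function(tr) {
    tr <- as.integer(tr)
    stopifnot(length(tr) == 3)
    names(tr) <- c("n", "ca", "c")
    tr
  })
  rm <- structure(
    list(donor_n = as.integer(donor_n), donor_h = as.integer(donor_h),
         acceptor_pos1 = as.integer(acceptor_pos1),
         acceptor_pos3 = as.integer(acceptor_pos3),
         calpha = calpha, backbone = backbone,
         gamma_residue = as.integer(gamma_residue)),
    class = "role_map"
  )
  if (!is.null(graph)) {
    validate_role_map(rm, graph)
  }
  rm
}

#' Validate a role map against a molecular graph
#'
#' Checks that all ids exist, that the donor hydrogen is bonded to the
#' donor nitrogen, and that both acceptors are carbonyl oxygens.
#'
#' @param roles A [role_map()].
#' @param g A [molecular_graph()].
#' @return `roles`, invisibly; errors otherwise.
#' @export
validate_role_map <- function(roles, g) {
  ids <- c(roles$donor_n, roles$donor_h, roles$acceptor_pos1,
           roles$acceptor_pos3, roles$calpha,
           unlist(roles$backbone, use.names = FALSE))
  ids <- ids[!is.na(ids)]
  if (any(ids < 1 | ids > nrow(g$atoms))) {
    stop("role map references atom ids outside the graph", call. = FALSE)
  }
  if (!roles$donor_h %in% .neighbors(g, roles$donor_n)) {
    stop("donor_h is not bonded to donor_n", call. = FALSE)
  }
  for (acc in c(roles$acceptor_pos1, roles$acceptor_pos3)) {
    if (g$atoms$element[acc] != "O") {
      stop("acceptor atom ", acc, " is not an oxygen", call. = FALSE)
    }
    nb <- g$bonds[g$bonds$a1 == acc | g$bonds$a2 == acc, ]
    if (!any(nb$order == 2)) {
      stop("acceptor atom ", acc, " is not a carbonyl oxygen", call. = FALSE)
    }
  }
  invisible(roles)
}

#' @export
print.role_map <- function(x, ...) {
  cat("<role_map> donor N", x$donor_n, "-H", x$donor_h,
      "; acceptors O", x$acceptor_pos1, " (pos 1), O", x$acceptor_pos3,
      " (pos 3); Calpha ", paste(x$calpha, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Read / write a role map as YAML
#'
#' @param path File path.
#' @return [read_role_map()] returns a [role_map()]; [write_role_map()]
#'   returns `path` invisibly.
#' @export
read_role_map <- function(path) {
  y <- yaml::read_yaml(path)
  role_map(
    donor_n = y$donor_n, donor_h = y$donor_h,
    acceptor_pos1 = y$acceptor_pos1, acceptor_pos3 = y$acceptor_pos3,
    calpha = unlist(y$calpha),
    backbone = purrr::map(y$backbone, unlist),
    gamma_residue = y$gamma_residue %||% 4L
  )
}

#' @rdname read_role_map
#' @param roles A [role_map()].
#' @export
write_role_map <- function(roles, path) {
  yaml::write_yaml(
    list(donor_n = roles$donor_n, donor_h = roles$donor_h,
         acceptor_pos1 = roles$acceptor_pos1,
         acceptor_pos3 = roles$acceptor_pos3,
         calpha = as.list(roles$calpha),
         backbone = purrr::map(roles$backbone, as.list),
         gamma_residue = roles$gamma_residue),
    path
  )
  invisible(path)
}

# ---- scaffold-specific derivation ------------------------------------------

#' Derive the role map of a THBC-DKP peptidomimetic graph
#'
#' Locates, by local connectivity rules, the atoms of the
#' tetrahydro-beta-carboline / diketopiperazine scaffold that emulate the
#' five positions of an alpha-turn: the C-terminal methylamide N-H (the
#' position-5 donor), the DKP carbonyl adjacent to the glycine-like
#' methylene (the position-3 acceptor closing the 7-ring), the Cbz
#' carbamate carbonyl (the position-1 acceptor closing the 13-ring), the
#' benzyl ether oxygen of the Cbz as the Calpha-1 surrogate, and the
#' N-methyl carbon as Calpha-5. The virtual backbone triples run
#' Cbz-NH-CH2-C6-N(ring)-C12a-C(=O)-N(DKP)-CH2-C(=O)-NHMe.
#'
#' The rules are written for this scaffold family; for other molecules
#' supply a [role_map()] by hand or via [read_role_map()].
#'
#' @param g A [molecular_graph()] of the scaffold (explicit hydrogens).
#' @return A validated [role_map()].
#' @export
derive_thbc_roles <- function(g) {
  el <- g$atoms$element
  h_count <- function(i) sum(el[.neighbors(g, i)] == "H")
  carbonyl_o <- function(i) {
    nb <- g$bonds[(g$bonds$a1 == i | g$bonds$a2 == i) & g$bonds$order == 2, ]
    o <- c(nb$a2[nb$a1 == i], nb$a1[nb$a2 == i])
    o[el[o] == "O"][1]
  }
  # methylamide N: one H, a CH3 neighbour and a carbonyl-C neighbour
  nh_cand <- which(purrr::map_lgl(seq_along(el), function(i) {
    el[i] == "N" && h_count(i) == 1 &&
      any(purrr::map_lgl(.neighbors(g, i), function(k) {
        el[k] == "C" && h_count(k) == 3
      })) &&
      any(purrr::map_lgl(.neighbors(g, i), function(k) .is_carbonyl_c(g, k)))
  }))
  if (length(nh_cand) != 1) {
    stop("could not locate a unique methylamide N-H on this graph",
         call. = FALSE)
  }
  nh <- nh_cand[1]
  h_me <- .neighbors(g, nh)[el[.neighbors(g, nh)] == "H"][1]
  nme_c <- .neighbors(g, nh)[purrr::map_lgl(.neighbors(g, nh), function(k) {
    el[k] == "C" && h_count(k) == 3
  })][1]
  cam <- .neighbors(g, nh)[purrr::map_lgl(.neighbors(g, nh), function(k) {
    .is_carbonyl_c(g, k)
  })][1]
  gly <- .neighbors(g, cam)[purrr::map_lgl(.neighbors(g, cam), function(k) {
    el[k] == "C" && h_count(k) == 2
  })][1]
  n2 <- .neighbors(g, gly)[el[.neighbors(g, gly)] == "N"][1]
  c1d <- setdiff(
    .neighbors(g, n2)[purrr::map_lgl(.neighbors(g, n2), function(k) {
      .is_carbonyl_c(g, k)
    })],
    cam
  )[1]
  c12a <- .neighbors(g, c1d)[el[.neighbors(g, c1d)] == "C"][1]
  c3 <- setdiff(.neighbors(g, n2)[el[.neighbors(g, n2)] == "C"],
                c(gly, c1d))[1]
  c4 <- .neighbors(g, c3)[purrr::map_lgl(.neighbors(g, c3), function(k) {
    .is_carbonyl_c(g, k)
  })][1]
  n5ring <- .neighbors(g, c4)[el[.neighbors(g, c4)] == "N"][1]
  c6 <- setdiff(.neighbors(g, n5ring), c(c4, c12a))[1]
  ch2 <- .neighbors(g, c6)[purrr::map_lgl(.neighbors(g, c6), function(k) {
    el[k] == "C" && h_count(k) == 2
  })][1]
  ncbz <- .neighbors(g, ch2)[el[.neighbors(g, ch2)] == "N"][1]
  cbz_c <- .neighbors(g, ncbz)[purrr::map_lgl(.neighbors(g, ncbz), function(k) {
    .is_carbonyl_c(g, k)
  })][1]
  benzyl_o <- .neighbors(g, cbz_c)[purrr::map_lgl(
    .neighbors(g, cbz_c),
    function(k) {
      el[k] == "O" &&
        !any(g$bonds$order[(g$bonds$a1 == k | g$bonds$a2 == k)] == 2)
    }
  )][1]
  if (anyNA(c(nh, h_me, nme_c, cam, gly, n2, c1d, c12a, c3, c4, n5ring, c6,
              ch2, ncbz, cbz_c, benzyl_o))) {
    stop("THBC-DKP role derivation failed; supply a role_map() manually",
         call. = FALSE)
  }
  role_map(
    donor_n = nh, donor_h = h_me,
    acceptor_pos1 = carbonyl_o(cbz_c),
    acceptor_pos3 = carbonyl_o(c1d),
    calpha = c(benzyl_o, ch2, c12a, gly, nme_c),
    backbone = list(
      `1` = c(NA, benzyl_o, cbz_c),
      `2` = c(ncbz, ch2, c6),
      `3` = c(n5ring, c12a, c1d),
      `4` = c(n2, gly, cam),
      `5` = c(nh, nme_c, NA)
    ),
    gamma_residue = 4L,
    graph = g
  )
}
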