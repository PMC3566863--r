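#' Monoisotopic masses of the supported elements
#'
#' Masses of the most abundant isotope, in Da. Hard-coded so that exact-mass
#' arithmetic is bit-stable across platforms and R versions.
#' @keywords internal
.isotope_mass <- c(
  C  = 12.0000000,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.97207069,
  F  = 18.99840322,
  Cl = 34.96885271,
  Br = 78.9183376
)

#' Parse a molecular-formula string
#'
#' Turns a formula such as `"C27H29N5O5"` into a named integer vector of
#' element counts (a *composition*). Hill order is not required on input;
#' [hill_formula()] renders the canonical string back.
#'
#' @param text A molecular-formula string, e.g. `"C6H12O6"`. An element
#'   symbol is one upper-case letter optionally followed by one lower-case
#'   letter; a missing count means 1. Multiple occurrences of an element
#'   are summed.
#' @return A named integer vector of class `"composition"`; names are
#'   element symbols, values are counts (all >= 1).
#' @examples
#' parse_formula("C27H29N5O5")
#' parse_formula("H2O")
#' @seealso [monoisotopic_mass()], [hill_formula()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) {
    stop("empty formula string", call. = FALSE)
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(nchar(matched)) != nchar(text)) {
    stop("formula does not match the element-count grammar: ", text,
         call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", matched)
  counts <- as.integer(ifelse(grepl("[0-9]+$", matched),
                              sub("^[A-Za-z]+", "", matched), "1"))
  if (any(counts <= 0)) {
    stop("zero or negative element count in: ", text, call. = FALSE)
  }
  unknown <- setdiff(elems, names(.isotope_mass))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  structure(as.integer(out), names = names(out), class = "composition")
}

#' Canonical Hill-order formula string
#'
#' @param c A `composition` (see [parse_formula()]) or a named count vector.
#' @return A single string: carbon first, hydrogen second, all other
#'   elements alphabetical (plain alphabetical if no carbon).
#' @examples
#' hill_formula(parse_formula("O5N5C27H29"))
#' @export
hill_formula <- function(c) {
  counts <- unclass(c)
  elems <- names(counts)
  if ("C" %in% elems) {
    ord <- c(intersect(c("C", "H"), elems), sort(setdiff(elems, c("C", "H"))))
  } else {
    ord <- sort(elems)
  }
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Monoisotopic (exact) mass of a composition
#'
#' Sum over elements of count times the most-abundant-isotope mass,
#' for the *neutral* molecule: no electron-mass correction is applied,
#' which is the convention under which printed HRMS "calcd" values for
#' EI `[M]+` spectra are quoted to four decimals.
#'
#' @param c A `composition` from [parse_formula()], or a named count vector.
#' @return Mass in Da (numeric scalar).
#' @examples
#' monoisotopic_mass(parse_formula("C27H29N5O5")) # 503.2169
#' @export
monoisotopic_mass <- function(c) {
  counts <- unclass(c)
  unknown <- setdiff(names(counts), names(.isotope_mass))
  if (length(unknown)) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(.isotope_mass[names(counts)] * counts)
}

#' @export
print.composition <- function(x, ...) {
  cat("<composition>", hill_formula(x), "\n")
  invisible(x)
}

#' @export
format.composition <- function(x, ...) hill_formula(x)
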