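# Built-in reference structures: the THBC-DKP peptidomimetic scaffold in
# both C6 epimers, reconstructed from its published IUPAC name, plus the
# published exact-mass reference table.

#' SMILES of the THBC-DKP peptidomimetic scaffold
#'
#' Benzyl (((3S,6S/R,12aS)-3-methyl-2-(2-(methylamino)-2-oxoethyl)-1,4-
#' dioxo-octahydropyrazino[1',2':1,6]pyrido[3,4-b]indol-6-yl)methyl)-
#' carbamate. The connectivity was reconstructed from the printed IUPAC
#' name (no machine-readable structure is deposited) and validated by
#' elemental formula and monoisotopic mass (C27H29N5O5, 503.2169 Da);
#' stereocentre annotations were assigned by CIP enumeration. `"1a"` is
#' the (3S,6S,12aS) diastereomer whose C6/C12a substituents are cis;
#' `"1b"` the (3S,6R,12aS) epimer.
#'
#' @param compound `"1a"` or `"1b"`.
#' @return A SMILES string.
#' @examples
#' thbc_dkp_smiles("1a")
#' @export
thbc_dkp_smiles <- function(compound = c("1a", "1b")) {
  compound <- match.arg(compound)
  switch(compound,
    "1a" = paste0("CNC(=O)CN1C(=O)[C@@H]2Cc3c([nH]c4ccccc34)",
                  "[C@H](CNC(=O)OCc3ccccc3)N2C(=O)[C@@H]1C"),
    "1b" = paste0("CNC(=O)CN1C(=O)[C@@H]2Cc3c([nH]c4ccccc34)",
                  "[C@@H](CNC(=O)OCc3ccccc3)N2C(=O)[C@@H]1C")
  )
}

#' Published exact-mass reference values
#'
#' The six high-resolution EI-MS "calcd" values of the scaffold series
#' (final methylamide, the tetrahydro-beta-carboline ester, the
#' N-alkylated alanine ester, its Fmoc acid, the coupled intermediate,
#' and the cyclized DKP ester), as printed: neutral-molecule
#' monoisotopic masses to four decimals.
#'
#' @return Tibble with columns `compound`, `formula`, `calcd_mass_da`.
#' @export
hrms_reference <- function() {
  tibble(
    compound = c("1a", "2", "3", "4", "5", "6"),
    formula = c("C27H29N5O5", "C22H23N3O4", "C14H19NO4",
                "C22H23NO6", "C44H44N4O9", "C28H30N4O6"),
    calcd_mass_da = c(503.2169, 393.1689, 265.1314,
                      397.1525, 772.3108, 518.2165)
  )
}

#' Published NMR hydrogen-bond evidence of the methylamide scaffold
#'
#' The four printed observables for the two exchangeable amide protons
#' of the final methylamide in CDCl3 at 2.0 mM: absolute temperature
#' coefficients over 263-328 K and chemical-shift responses to a 0-30%
#' DMSO titration.
#'
#' @return Tibble with columns `label`, `abs_temp_coef_ppb_K`,
#'   `titration_delta_ppm`, `delta_ppm_cdcl3`.
#' @export
nmr_reference <- function() {
  tibble(
    label = c("NHMe", "NHCbz"),
    abs_temp_coef_ppb_K = c(7.0, 2.3),
    titration_delta_ppm = c(0.24, 0.82),
    delta_ppm_cdcl3 = c(6.78, 5.53)
  )
}
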