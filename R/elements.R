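#' @keywords internal
"_PACKAGE"

## Atomic masses (amu), atomic numbers, and van der Waals radii (Angstrom)
## for the elements that occur in biomolecular simulations.  Unknown
## elements fall back to carbon-like defaults with a warning.

.element_table <- data.frame(
  element = c("H", "C", "N", "O", "F", "NA", "MG", "P", "S", "CL",
              "K", "CA", "FE", "ZN", "BR", "I"),
  mass    = c(1.008, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
              30.974, 32.06, 35.45, 39.098, 40.078, 55.845, 65.38,
              79.904, 126.904),
  number  = c(1, 6, 7, 8, 9, 11, 12, 15, 16, 17, 19, 20, 26, 30, 35, 53),
  vdw     = c(1.2, 1.7, 1.55, 1.52, 1.47, 2.27, 1.73, 1.8, 1.8, 1.75,
              2.75, 2.31, 2.0, 1.39, 1.85, 1.98),
  stringsAsFactors = FALSE
)

#' Atomic mass lookup
#'
#' @param element character vector of element symbols (upper case).
#' @return numeric vector of masses in amu; unknown elements get 12.011
#'   with a warning.
#' @keywords internal
element_mass <- function(element) {
  idx <- match(toupper(element), .element_table$element)
  if (anyNA(idx)) {
    warning("unknown element(s): ",
            paste(unique(element[is.na(idx)]), collapse = ", "),
            "; using carbon mass")
  }
  out <- .element_table$mass[idx]
  out[is.na(out)] <- 12.011
  out
}

#' @keywords internal
element_number <- function(element) {
  idx <- match(toupper(element), .element_table$element)
  out <- .element_table$number[idx]
  out[is.na(out)] <- 6
  out
}

#' Van der Waals radius lookup
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom; unknown elements get 1.7
#'   with a warning.
#' @keywords internal
element_vdw <- function(element) {
  idx <- match(toupper(element), .element_table$element)
  if (anyNA(idx)) {
    warning("unknown element(s) for vdW radius; using 1.7 Angstrom")
  }
  out <- .element_table$vdw[idx]
  out[is.na(out)] <- 1.7
  out
}

#' Guess an element symbol from a PDB atom name
#'
#' First tries the standard two-character element field convention; for
#' plain names the first alphabetic character is used (works for H, C, N,
#' O, P, S which cover simulation topologies).
#' @keywords internal
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- toupper(gsub("[^A-Z]", "", toupper(nm)))
    if (nchar(nm) == 0L) return("C")
    two <- substr(nm, 1, 2)
    if (two %in% c("CL", "BR", "NA", "MG", "FE", "ZN")) return(two)
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

.standard_amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

.water_resnames <- c("TIP3", "HOH", "WAT", "SPC", "TIP4")
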