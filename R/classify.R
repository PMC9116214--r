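#' Map residue names to the contact-feature residue alphabet
#'
#' The contact featurization groups protein atoms by the residue they belong
#' to, using the 20 standard amino acids plus a catch-all class `OTH` for
#' non-standard residues (e.g. `MSE`), ligands, or unrecognized codes.
#' Matching is case-insensitive and the function is total: every input maps
#' to exactly one class.
#'
#' @param residue_name Character vector of 3-letter residue codes.
#' @return Character vector of the same length with values in
#'   [residue_classes()].
#' @examples
#' classify_residue(c("ASP", "asp", "MSE", "LIG"))
#' @seealso [classify_element()], [feature_schema()]
#' @export
classify_residue <- function(residue_name) {
  up <- toupper(trimws(as.character(residue_name)))
  ifelse(up %in% RESIDUE_CLASSES[1:20], up, "OTH")
}

#' Map element symbols to the ligand-element alphabet
#'
#' Ligand heavy atoms are classed as C, N, O, S, P, HAL (the halogens
#' F/Cl/Br/I pooled) or OTH. Hydrogens never reach the featurizer (the
#' readers enforce a heavy-atom contract), so no H class exists.
#'
#' @param symbol Character vector of element symbols (case-insensitive).
#' @return Character vector with values in [element_classes()].
#' @examples
#' classify_element(c("Cl", "Fe", "N"))
#' @export
classify_element <- function(symbol) {
  up <- toupper(trimws(as.character(symbol)))
  out <- ifelse(up %in% c("C", "N", "O", "S", "P"), up,
    ifelse(up %in% HALOGENS, "HAL", "OTH")
  )
  out
}

#' Feature alphabets
#'
#' @return `residue_classes()` returns the 21 residue classes (20 standard
#'   amino acids, alphabetical, then `OTH`); `element_classes()` returns the
#'   7 ligand element classes in canonical order (C, N, O, S, P, HAL, OTH).
#' @export
residue_classes <- function() RESIDUE_CLASSES

#' @rdname residue_classes
#' @export
element_classes <- function() ELEMENT_CLASSES
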