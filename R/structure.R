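#' Atom in a crystal structure
#'
#' @param label Unique atom label, e.g. \code{"O1"}.
#' @param element Chemical symbol (H, C, N, O supported by the synthetic
#'   density source; any symbol is carried through the model layer).
#' @param frac_pos Length-3 fractional coordinates.
#' @param occupancy Site occupancy in (0, 1].
#' @param uiso Isotropic displacement parameter U (angstrom^2), used when
#'   \code{uaniso} is \code{NULL}.
#' @param uaniso Optional length-6 CIF-convention anisotropic U^ij in
#'   (U11, U22, U33, U12, U13, U23) order (angstrom^2).
#' @param gc3 Optional length-10 third-order Gram-Charlier tensor C^{jkl}
#'   (unique components, see \code{\link{gram_charlier}} for the ordering).
#' @param gc4 Optional length-15 fourth-order Gram-Charlier tensor D^{jklm}.
#' @return Object of class \code{atom}.
#' @export
atom <- function(label, element, frac_pos, occupancy = 1,
                 uiso = 0, uaniso = NULL, gc3 = NULL, gc4 = NULL) {
  stopifnot(length(frac_pos) == 3)
  if (occupancy <= 0 || occupancy > 1)
    stop("occupancy must lie in (0, 1]")
  if (!is.null(uaniso) && length(uaniso) != 6)
    stop("uaniso must have 6 components")
  if (!is.null(gc3) && length(gc3) != 10)
    stop("gc3 must have 10 unique components")
  if (!is.null(gc4) && length(gc4) != 15)
    stop("gc4 must have 15 unique components")
  structure(list(label = as.character(label), element = as.character(element),
                 frac_pos = as.numeric(frac_pos), occupancy = occupancy,
                 uiso = uiso, uaniso = if (is.null(uaniso)) NULL else as.numeric(uaniso),
                 gc3 = if (is.null(gc3)) NULL else as.numeric(gc3),
                 gc4 = if (is.null(gc4)) NULL else as.numeric(gc4)),
            class = "atom")
}

#' Crystal structure model
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param symmetry List of \code{\link{symop}} objects (must contain the
#'   identity; checked for closure).
#' @param atoms List of \code{\link{atom}} objects (asymmetric unit); labels
#'   must be unique.
#' @param wavelength Radiation wavelength in angstrom.
#' @return Object of class \code{crystal_structure}.
#' @export
crystal_structure <- function(cell, symmetry = list(symop_identity()),
                              atoms = list(), wavelength = 0.71073) {
  stopifnot(inherits(cell, "unit_cell"))
  check_symmetry_group(symmetry)
  labels <- vapply(atoms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("atom labels must be unique")
  # warn (do not fail) on non-positive-semidefinite anisotropic U
  for (at in atoms) {
    if (!is.null(at$uaniso)) {
      ev <- eigen(u_cif_to_cart(at$uaniso, cell), symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10)
        warning(sprintf("atom %s: anisotropic U is not positive semidefinite", at$label))
    }
  }
  structure(list(cell = cell, symmetry = symmetry, atoms = atoms,
                 wavelength = wavelength),
            class = "crystal_structure")
}

#' @export
print.crystal_structure <- function(x, ...) {
  cat(sprintf("crystal structure: %d atom(s) in the asymmetric unit, %d symmetry op(s)\n",
              length(x$atoms), length(x$symmetry)))
  print(x$cell)
  for (at in x$atoms)
    cat(sprintf("  %-5s %-2s (%8.5f %8.5f %8.5f) occ=%.3f %s\n",
                at$label, at$element, at$frac_pos[1], at$frac_pos[2], at$frac_pos[3],
                at$occupancy,
                if (is.null(at$uaniso)) sprintf("Uiso=%.5f", at$uiso) else "aniso"))
  invisible(x)
}

structure_labels <- function(structure)
  vapply(structure$atoms, `[[`, character(1), "label")

get_atom <- function(structure, label) {
  i <- match(label, structure_labels(structure))
  if (is.na(i)) stop("no atom with label ", label)
  structure$atoms[[i]]
}

#' Total electron count of the unit cell
#'
#' Sum over the P1 expansion of multiplicity x occupancy x Z.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @return Scalar electron count.
#' @export
cell_electron_count <- function(structure) {
  p1 <- expand_to_p1(structure)
  sum(vapply(p1, function(rec)
    rec$atom$occupancy * element_number(rec$atom$element), numeric(1)))
}

element_number <- function(element) {
  z <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
         F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15,
         S = 16, Cl = 17)
  v <- z[element]
  if (any(is.na(v))) stop("unknown element symbol: ", paste(element[is.na(v)], collapse = ", "))
  unname(v)
}
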