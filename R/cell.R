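#' Unit cell
#'
#' Construct a unit cell from lengths (angstrom) and angles (degrees).
#' The orthogonalization convention used throughout the package places
#' \code{a} along Cartesian x and \code{b} in the x-y plane (the standard
#' crystallographic convention).
#'
#' @param a,b,c Cell edge lengths in angstrom, all > 0.
#' @param alpha,beta,gamma Cell angles in degrees, each in (0, 180).
#' @return An object of class \code{unit_cell} with fields \code{a}, \code{b},
#'   \code{c}, \code{alpha}, \code{beta}, \code{gamma} and \code{volume}
#'   (angstrom^3).
#' @examples
#' cl <- unit_cell(5.78, 6.15, 12.32, 85.2, 92.1, 104.3)
#' cl$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (any(c(a, b, c) <= 0))
    stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0)
    stop("invalid cell: angles give non-positive volume")
  vol <- a * b * c * sqrt(arg)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 volume = vol),
            class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f A, alpha=%.3f beta=%.3f gamma=%.3f deg, V=%.3f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Orthogonalization matrix
#'
#' Matrix \code{A} mapping fractional to Cartesian coordinates,
#' \code{x_cart = A \%*\% x_frac}, with a along x and b in the x-y plane.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return 3x3 numeric matrix (angstrom).
#' @export
orthogonalization_matrix <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  v <- cell$volume
  matrix(c(cell$a, cell$b * cg, cell$c * cb,
           0,      cell$b * sg, cell$c * (ca - cb * cg) / sg,
           0,      0,           v / (cell$a * cell$b * sg)),
         nrow = 3, byrow = TRUE)
}

#' Direct and reciprocal metric tensors
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return List with \code{G} (direct metric, angstrom^2) and \code{Gstar}
#'   (reciprocal metric, angstrom^-2), both symmetric; \code{G \%*\% Gstar}
#'   is the identity.
#' @examples
#' metric_tensors(unit_cell(2, 2, 2))$G  # diag(4, 4, 4)
#' @export
metric_tensors <- function(cell) {
  A <- orthogonalization_matrix(cell)
  G <- crossprod(A)
  G <- (G + t(G)) / 2
  d <- det(G)
  if (!is.finite(d) || d <= 0)
    stop("invalid cell: singular direct metric tensor")
  Gstar <- solve(G)
  Gstar <- (Gstar + t(Gstar)) / 2
  list(G = G, Gstar = Gstar)
}

#' Reciprocal cell edge lengths
#'
#' a*, b*, c* in angstrom^-1 (square roots of the reciprocal metric diagonal).
#'
#' @param cell A \code{\link{unit_cell}}.
#' @return Numeric length-3 vector.
#' @export
reciprocal_lengths <- function(cell) {
  sqrt(diag(metric_tensors(cell)$Gstar))
}

#' Fractional to Cartesian coordinates
#'
#' @param x Fractional coordinates: length-3 vector or n x 3 matrix.
#' @param cell A \code{\link{unit_cell}}.
#' @return Cartesian coordinates (angstrom), same shape as the input.
#' @export
frac_to_cart <- function(x, cell) {
  A <- orthogonalization_matrix(cell)
  if (is.matrix(x)) t(A %*% t(x)) else as.numeric(A %*% x)
}

#' Cartesian to fractional coordinates
#'
#' @inheritParams frac_to_cart
#' @param x Cartesian coordinates (angstrom): length-3 vector or n x 3 matrix.
#' @return Fractional coordinates, same shape as the input.
#' @export
cart_to_frac <- function(x, cell) {
  Ai <- solve(orthogonalization_matrix(cell))
  if (is.matrix(x)) t(Ai %*% t(x)) else as.numeric(Ai %*% x)
}

# Internal: unique-component order for U^ij used throughout the package:
# (U11, U22, U33, U12, U13, U23).
u6_pairs <- function() {
  cbind(i = c(1L, 2L, 3L, 1L, 1L, 2L),
        j = c(1L, 2L, 3L, 2L, 3L, 3L))
}

#' Six-component U to symmetric matrix
#'
#' Component order is (U11, U22, U33, U12, U13, U23).
#'
#' @param u6 Numeric length-6 vector.
#' @return Symmetric 3x3 matrix.
#' @export
u6_to_matrix <- function(u6) {
  stopifnot(length(u6) == 6)
  matrix(c(u6[1], u6[4], u6[5],
           u6[4], u6[2], u6[6],
           u6[5], u6[6], u6[3]), nrow = 3)
}

#' Symmetric matrix to six-component U
#'
#' @param m Symmetric 3x3 matrix.
#' @return Numeric length-6 vector in (U11, U22, U33, U12, U13, U23) order.
#' @export
matrix_to_u6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' CIF-convention U^ij to Cartesian displacement matrix
#'
#' Converts the six CIF components U^ij (referred to the reciprocal basis)
#' to the symmetric 3x3 displacement matrix in the Cartesian frame:
#' \code{U_cart = A N U_cif N t(A)} with \code{N = diag(a*, b*, c*)} and
#' \code{A} the orthogonalization matrix.
#'
#' @param u_cif Length-6 vector (U11, U22, U33, U12, U13, U23), angstrom^2.
#' @param cell A \code{\link{unit_cell}}.
#' @return Symmetric 3x3 matrix (angstrom^2).
#' @export
u_cif_to_cart <- function(u_cif, cell) {
  if (any(!is.finite(u_cif))) stop("non-finite U components")
  A <- orthogonalization_matrix(cell)
  N <- diag(reciprocal_lengths(cell))
  M <- A %*% N
  U <- M %*% u6_to_matrix(u_cif) %*% t(M)
  (U + t(U)) / 2
}

#' Cartesian displacement matrix to CIF-convention U^ij
#'
#' Inverse of \code{\link{u_cif_to_cart}}.
#'
#' @param u_cart Symmetric 3x3 matrix (angstrom^2).
#' @param cell A \code{\link{unit_cell}}.
#' @return Length-6 vector (U11, U22, U33, U12, U13, U23).
#' @export
u_cart_to_cif <- function(u_cart, cell) {
  A <- orthogonalization_matrix(cell)
  N <- diag(reciprocal_lengths(cell))
  Mi <- solve(A %*% N)
  matrix_to_u6(Mi %*% u_cart %*% t(Mi))
}

#' Equivalent isotropic displacement parameter
#'
#' U_eq = trace(U_cart) / 3.
#'
#' @param u_cif Length-6 CIF-convention U vector.
#' @param cell A \code{\link{unit_cell}}.
#' @return Scalar U_eq in angstrom^2.
#' @export
u_equiv <- function(u_cif, cell) {
  sum(diag(u_cif_to_cart(u_cif, cell))) / 3
}
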