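#' Debye-Waller temperature factor
#'
#' Anisotropic form
#' \code{T = exp(-2 pi^2 sum_ij h_i h_j a*_i a*_j U^ij)} with the CIF
#' convention U^ij, or isotropic \code{T = exp(-8 pi^2 U (sin theta /
#' lambda)^2)}.
#'
#' @param hkl Integer matrix (n x 3) or length-3 vector.
#' @param atom An \code{\link{atom}} (its \code{uaniso} is used when present,
#'   \code{uiso} otherwise).
#' @param cell A \code{\link{unit_cell}}.
#' @return Numeric vector of attenuation factors in (0, 1] (for physically
#'   meaningful, positive semidefinite U).
#' @export
debye_waller <- function(hkl, atom, cell) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  if (!is.null(atom$uaniso)) {
    M <- dw_quadratic_matrix(atom$uaniso, cell)
    exp(-2 * pi^2 * rowSums((hkl %*% M) * hkl))
  } else {
    s <- resolution(hkl, cell)
    exp(-8 * pi^2 * atom$uiso * s^2)
  }
}

# N U N with N = diag(a*, b*, c*): the quadratic form h' (N U N) h gives the
# anisotropic exponent
dw_quadratic_matrix <- function(u6, cell) {
  N <- diag(reciprocal_lengths(cell))
  N %*% u6_to_matrix(u6) %*% N
}

#' Gram-Charlier anharmonic multiplier
#'
#' Third/fourth-order correction to the harmonic temperature factor:
#' \deqn{M(h) = 1 + \frac{(2\pi i)^3}{3!} C^{jkl} h_j h_k h_l
#'             + \frac{(2\pi i)^4}{4!} D^{jklm} h_j h_k h_l h_m,}
#' indices in the reciprocal-lattice basis. The tensors are stored as unique
#' components with multiplicities; the ordering is that of the internal
#' index tables (C: 111, 222, 333, 112, 122, 113, 133, 223, 233, 123;
#' D: 1111, 2222, 3333, 1112, 1222, 1113, 1333, 2223, 2333, 1122, 1133,
#' 2233, 1123, 1223, 1233).
#'
#' @param hkl Integer matrix (n x 3) or length-3 vector.
#' @param gc3 Length-10 numeric vector of C^{jkl} unique components, or
#'   \code{NULL}.
#' @param gc4 Length-15 numeric vector of D^{jklm} unique components, or
#'   \code{NULL}.
#' @return Complex vector of multipliers (1 when both tensors vanish; the
#'   third-order term is purely imaginary).
#' @export
gram_charlier <- function(hkl, gc3 = NULL, gc4 = NULL) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  out <- rep(1 + 0i, nrow(hkl))
  if (!is.null(gc3) && any(gc3 != 0)) {
    tab <- gc3_index_table()
    s3 <- numeric(nrow(hkl))
    for (r in seq_len(nrow(tab$idx))) {
      ix <- tab$idx[r, ]
      s3 <- s3 + tab$mult[r] * gc3[r] * hkl[, ix[1]] * hkl[, ix[2]] * hkl[, ix[3]]
    }
    out <- out + (2i * pi)^3 / 6 * s3
  }
  if (!is.null(gc4) && any(gc4 != 0)) {
    tab <- gc4_index_table()
    s4 <- numeric(nrow(hkl))
    for (r in seq_len(nrow(tab$idx))) {
      ix <- tab$idx[r, ]
      s4 <- s4 + tab$mult[r] * gc4[r] *
        hkl[, ix[1]] * hkl[, ix[2]] * hkl[, ix[3]] * hkl[, ix[4]]
    }
    out <- out + (2i * pi)^4 / 24 * s4
  }
  out
}

#' Structure factors from form factors and displacement models
#'
#' \deqn{F_c(h) = \sum_{images} occ \cdot f(h) \cdot T(R^T h) \cdot
#'   M_{GC}(R^T h) \cdot e^{2\pi i h\cdot(R x + t)}}
#' summed over the P1 expansion. Each image carries its own atom-centred
#' form factor; the displacement and Gram-Charlier tensors of the generating
#' atom are evaluated at the back-rotated index \code{R^T h}, which is how
#' symmetry-generated images inherit the generator's (an)harmonic model.
#'
#' @param structure A \code{\link{crystal_structure}} (supplies the
#'   generating atoms' parameters).
#' @param images P1 expansion from \code{\link{expand_to_p1}} (or the
#'   \code{$images} of a form-factor provider result).
#' @param ff Complex n_hkl x n_images matrix of atom-centred form factors.
#' @param hkl Integer matrix (n_hkl x 3).
#' @return Complex vector of structure factors.
#' @export
calc_structure_factors <- function(structure, images, ff, hkl) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  if (ncol(ff) != length(images) || nrow(ff) != nrow(hkl))
    stop("form-factor matrix must be n_hkl x n_images")
  fc <- rep(0 + 0i, nrow(hkl))
  cell <- structure$cell
  for (im in seq_along(images)) {
    rec <- images[[im]]
    gen <- structure$atoms[[rec$gen]]
    W <- rec$op$R; tt <- rec$op$t
    hp <- hkl %*% W                       # row i holds t(W) %*% h_i
    pos <- as.numeric(W %*% gen$frac_pos) + tt
    phase <- exp(2i * pi * as.numeric(hkl %*% pos))
    Tdw <- debye_waller_rot(hp, gen, cell)
    gc <- gram_charlier(hp, gen$gc3, gen$gc4)
    fc <- fc + gen$occupancy * ff[, im] * Tdw * gc * phase
  }
  fc
}

# Debye-Waller at already-rotated indices (hp = h %*% W)
debye_waller_rot <- function(hp, atom, cell) {
  if (!is.null(atom$uaniso)) {
    M <- dw_quadratic_matrix(atom$uaniso, cell)
    exp(-2 * pi^2 * rowSums((hp %*% M) * hp))
  } else {
    s <- resolution(hp, cell)
    exp(-8 * pi^2 * atom$uiso * s^2)
  }
}

#' Secondary-extinction correction
#'
#' Squared form of the SHELXL Fc* convention:
#' \deqn{F_c^{2,corr} = F_c^2\,[1 + 0.001\,x\,F_c^2\,\lambda^3 /
#'   \sin 2\theta]^{-1/2}.}
#' Reflections with sin(2 theta) = 0 are left uncorrected; x = 0 is the
#' identity.
#'
#' @param fc2 Calculated intensities Fc^2.
#' @param hkl Integer matrix (n x 3).
#' @param wavelength Wavelength in angstrom.
#' @param cell A \code{\link{unit_cell}}.
#' @param x Extinction parameter, >= 0 for a physical correction.
#' @return Corrected Fc^2 values.
#' @export
apply_extinction <- function(fc2, hkl, wavelength, cell, x) {
  fc2 * (1 + extinction_coef(hkl, wavelength, cell, x) * fc2)^(-0.5)
}

# 0.001 x lambda^3 / sin(2 theta) per reflection; zero where sin 2theta = 0
extinction_coef <- function(hkl, wavelength, cell, x) {
  s <- resolution(hkl, cell)
  st <- pmin(s * wavelength, 1)
  s2t <- 2 * st * sqrt(pmax(1 - st^2, 0))
  out <- numeric(length(s))
  ok <- s2t > 1e-12
  out[ok] <- 0.001 * x * wavelength^3 / s2t[ok]
  out
}

#' Closed-form optimal scale factor
#'
#' Minimizer of \code{sum w (Fo^2 - k Fc^2)^2} with w = 1/sigma^2:
#' \code{k = sum(w Fo^2 Fc^2) / sum(w Fc^4)}.
#'
#' @param fo2 Observed intensities.
#' @param sigma Standard uncertainties sigma(Fo^2).
#' @param fc2 Calculated intensities.
#' @return Scalar k.
#' @export
optimal_scale <- function(fo2, sigma, fc2) {
  w <- 1 / sigma^2
  den <- sum(w * fc2^2)
  if (den <= 0) stop("all Fc^2 are zero; scale undefined")
  sum(w * fo2 * fc2) / den
}

#' Weighted R factor on intensities
#'
#' \deqn{wR_2 = \sqrt{\sum w (F_o^2 - k F_c^2)^2 / \sum w (F_o^2)^2}},
#' with w = 1/sigma^2 (no refinable weighting scheme).
#'
#' @param fo2 Observed intensities.
#' @param sigma Standard uncertainties sigma(Fo^2).
#' @param fc2 Calculated intensities (extinction-corrected if applicable).
#' @param k Scale factor.
#' @return Scalar wR2 (dimensionless, >= 0).
#' @export
wr2 <- function(fo2, sigma, fc2, k) {
  w <- 1 / sigma^2
  den <- sum(w * fo2^2)
  if (den <= 0) stop("sum of weighted Fo^4 is zero; wR2 undefined")
  sqrt(sum(w * (fo2 - k * fc2)^2) / den)
}
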