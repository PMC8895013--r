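#' Deterministic toy crystal structures
#'
#' Small cells (edges below 12 angstrom, at most 6 atoms, elements from
#' H/C/N/O) exercising the refinement pathways:
#' \describe{
#'   \item{\code{diatomic_P1}}{a C-H fragment in P1 (the minimal aspherical
#'     test case: one polar bond).}
#'   \item{\code{bent_triatomic_P1}}{a water-like O-H2 fragment in P1.}
#'   \item{\code{inversion_pair_P-1}}{one N atom on a general position of
#'     P-1, expanding to a centrosymmetric pair.}
#'   \item{\code{special_position_toy}}{P-1 with an O atom fixed on the
#'     inversion centre plus a general-position C-H fragment.}
#' }
#'
#' @param kind Structure kind (see above).
#' @param seed Reserved for seeded variants; the shipped geometries are
#'   fixed constants and ignore it.
#' @return A \code{\link{crystal_structure}}.
#' @export
make_toy_structure <- function(kind = c("diatomic_P1", "bent_triatomic_P1",
                                        "inversion_pair_P-1",
                                        "special_position_toy"),
                               seed = NULL) {
  kind <- match.arg(kind)
  p1 <- list(symop_identity())
  pbar1 <- list(symop_identity(), symop(-diag(3)))
  if (kind == "diatomic_P1") {
    cell <- unit_cell(6.0, 6.5, 7.0)
    # C-H bond of 1.09 A along the (1,1,0) direction
    u <- c(1, 1, 0) / sqrt(2)
    dx <- cart_to_frac(1.09 * u, cell)
    atoms <- list(
      atom("C1", "C", c(0.30, 0.32, 0.35), uaniso = c(0.010, 0.012, 0.011, 0.001, 0.000, -0.001)),
      atom("H1", "H", c(0.30, 0.32, 0.35) + dx, uaniso = c(0.020, 0.024, 0.022, 0.002, -0.001, 0.001))
    )
    return(crystal_structure(cell, p1, atoms))
  }
  if (kind == "bent_triatomic_P1") {
    cell <- unit_cell(6.0, 6.0, 6.5)
    r_oh <- 0.96
    half <- 104.5 / 2 * pi / 180
    o <- c(0.40, 0.40, 0.42)
    h1 <- cart_to_frac(r_oh * c(sin(half), cos(half), 0), cell)
    h2 <- cart_to_frac(r_oh * c(-sin(half), cos(half), 0), cell)
    atoms <- list(
      atom("O1", "O", o, uaniso = c(0.008, 0.009, 0.010, 0.000, 0.001, 0.000)),
      atom("H1", "H", o + h1, uaniso = c(0.018, 0.020, 0.022, 0.001, 0.000, 0.000)),
      atom("H2", "H", o + h2, uaniso = c(0.019, 0.021, 0.020, -0.001, 0.000, 0.001))
    )
    return(crystal_structure(cell, p1, atoms))
  }
  if (kind == "inversion_pair_P-1") {
    cell <- unit_cell(7.0, 7.5, 8.0, 92, 95, 88)
    atoms <- list(
      atom("N1", "N", c(0.10, 0.20, 0.30), uaniso = c(0.010, 0.011, 0.012, 0.001, -0.001, 0.002))
    )
    return(crystal_structure(cell, pbar1, atoms))
  }
  # special_position_toy: O on the inversion centre (multiplicity 1)
  cell <- unit_cell(7.0, 7.0, 7.5)
  u <- c(0, 1, 1) / sqrt(2)
  dx <- cart_to_frac(1.09 * u, cell)
  atoms <- list(
    atom("O1", "O", c(0, 0, 0), uaniso = c(0.009, 0.010, 0.011, 0.001, 0.000, 0.000)),
    atom("C1", "C", c(0.25, 0.18, 0.30), uaniso = c(0.011, 0.012, 0.010, 0.000, 0.001, -0.001)),
    atom("H1", "H", c(0.25, 0.18, 0.30) + dx, uaniso = c(0.022, 0.020, 0.024, 0.001, 0.000, 0.000))
  )
  crystal_structure(cell, pbar1, atoms)
}

#' Enumerate reflections to a resolution limit
#'
#' All hkl with 0 < sin(theta)/lambda <= 1/(2 d_min), restricted to one
#' hemisphere (no Friedel mates: h > 0, or h = 0 and k > 0, or h = k = 0
#' and l > 0), sorted by resolution and then lexicographically.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param d_min Resolution limit in angstrom (> 0).
#' @return Integer matrix (n x 3); zero rows when \code{d_min} exceeds the
#'   largest lattice spacing.
#' @export
enumerate_hkl <- function(cell, d_min) {
  stopifnot(d_min > 0)
  smax <- 1 / (2 * d_min)
  Gs <- metric_tensors(cell)$Gstar
  m <- floor(2 * smax / sqrt(min(eigen(Gs, symmetric = TRUE, only.values = TRUE)$values)))
  if (m < 1) return(matrix(integer(0), 0, 3))
  g <- as.matrix(expand.grid(h = -m:m, k = -m:m, l = -m:m))
  hemi <- g[, 1] > 0 | (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  g <- g[hemi, , drop = FALSE]
  s <- resolution(g, cell)
  keep <- s > 0 & s <= smax
  g <- g[keep, , drop = FALSE]
  s <- s[keep]
  ord <- order(s, g[, 1], g[, 2], g[, 3])
  unname(g[ord, , drop = FALSE])
}

#' Simulate a reflection data set from a structure and density source
#'
#' Computes model intensities through the full form-factor pipeline at the
#' given (truth) geometry and adds seeded multiplicative Gaussian noise:
#' \code{Fo2 = k_true * Fc^2 * (1 + eta * xi)} with xi standard normal, and
#' \code{sigma = k_true * Fc^2 * eta + floor} where the floor is
#' 0.01 x median(k_true * Fc^2). Zero noise returns \code{Fo2 = k_true *
#' Fc^2} exactly. Identical spec + seed gives bit-identical output.
#'
#' @param structure The generating (truth) \code{\link{crystal_structure}}.
#' @param source A \code{\link{synthetic_density_source}}; \code{NULL} or
#'   \code{"iam"} uses the spherical pro-atom form factors.
#' @param d_min Resolution limit in angstrom (default 0.6).
#' @param noise Fractional noise level eta >= 0 (default 0).
#' @param seed Integer seed for the noise generator (default 1).
#' @param k_true True scale factor (default 1).
#' @param grid_spacing Density grid spacing for the aspherical pipeline
#'   (default 0.1 angstrom).
#' @param interp_factor Fourier-interpolation factor (default 1).
#' @return A \code{\link{reflection_set}}; the attribute \code{"fc"} carries
#'   the generating complex structure factors and \code{"k_true"} the scale.
#' @export
simulate_reflections <- function(structure, source = NULL, d_min = 0.6,
                                 noise = 0, seed = 1, k_true = 1,
                                 grid_spacing = 0.1, interp_factor = 1) {
  stopifnot(d_min > 0, noise >= 0)
  hkl <- enumerate_hkl(structure$cell, d_min)
  if (nrow(hkl) == 0) stop("no reflections inside the resolution limit")
  if (is.null(source) || identical(source, "iam")) {
    if (is.null(source)) source <- synthetic_density_source("spherical_promolecule")
    ffr <- ff_iam(structure, source, hkl)
  } else if (identical(source$kind, "spherical_promolecule")) {
    ffr <- ff_iam(structure, source, hkl)
  } else {
    ffr <- ff_from_source(structure, source, hkl, spacing = grid_spacing,
                          interp_factor = interp_factor)
  }
  fc <- calc_structure_factors(structure, ffr$images, ffr$ff, hkl)
  fc2 <- Mod(fc)^2
  ideal <- k_true * fc2
  floor_sig <- 0.01 * stats::median(ideal)
  sig <- ideal * noise + floor_sig
  if (noise > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    xi <- stats::rnorm(length(fc2))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    fo2 <- ideal * (1 + noise * xi)
  } else {
    fo2 <- ideal
  }
  rs <- reflection_set(hkl, fo2, sig, wavelength = structure$wavelength)
  attr(rs, "fc") <- fc
  attr(rs, "k_true") <- k_true
  rs
}
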