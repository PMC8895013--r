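#' Synthetic density source
#'
#' A density source supplies, for a structure and target grid shape, (a) the
#' valence electron density of the whole cell on a periodic grid and (b)
#' per-element spherical frozen-core and pro-atom (reference) radial
#' densities. The frozen-core density is excluded from both the partitioned
#' density and the Hirshfeld weights and is instead assigned completely to
#' its atom through a Fourier-Bessel transform.
#'
#' The synthetic source stands in for an external periodic electronic-
#' structure engine so that the whole pipeline runs self-contained:
#' \describe{
#'   \item{\code{spherical_promolecule}}{valence density = superposition of
#'     the per-element spherical pro-atom valence densities (Gaussian-shell
#'     mixtures with tabulated electron counts).}
#'   \item{\code{aspherical_deformation}}{adds, per flagged bond A-B, a
#'     dipolar deformation \code{p * ((r - x_A) . u) * exp(-beta |r - x_A|^2)}
#'     (u the A-to-B unit vector) to atom A's density. The deformation
#'     integrates to zero (electron count conserved) and shifts the atom's
#'     density centroid along the bond by the closed-form amount returned by
#'     \code{\link{deformation_centroid_shift}}.}
#' }
#'
#' @param kind \code{"spherical_promolecule"} or
#'   \code{"aspherical_deformation"}.
#' @param bonds For the aspherical source: data frame with columns
#'   \code{from} (deformed atom label), \code{to} (bond partner label) and
#'   optionally \code{p} (deformation amplitude, e / angstrom^4; default
#'   \code{p}).
#' @param p Default deformation amplitude (default 0.5).
#' @param beta Radial envelope exponent in angstrom^-2 (default 4).
#' @param radial_n Points of the exponential radial grid for the core and
#'   pro-atom tables (default 2^13 + 1).
#' @return Object of class \code{density_source} with closures
#'   \code{proatom(element)}, \code{core(element)} and
#'   \code{valence_grid(atoms, shape, cell)}.
#' @export
synthetic_density_source <- function(kind = c("spherical_promolecule",
                                              "aspherical_deformation"),
                                     bonds = NULL, p = 0.5, beta = 4,
                                     radial_n = 2^13 + 1) {
  kind <- match.arg(kind)
  grid <- radial_grid_exp(n = radial_n)
  if (kind == "aspherical_deformation") {
    if (is.null(bonds) || nrow(bonds) == 0)
      stop("aspherical_deformation source requires a bonds data frame")
    if (is.null(bonds$p)) bonds$p <- p
  }
  proatom <- function(element)
    shell_spherical_density(synthetic_element_shells(element)$valence, grid)
  core <- function(element)
    shell_spherical_density(synthetic_element_shells(element)$core, grid)
  valence_grid <- function(atoms, shape, cell) {
    pro_d <- proatom_table(atoms, proatom)
    pm <- promolecule_on_grid(atoms, pro_d, shape, cell)
    vals <- pm$total$values
    if (kind == "aspherical_deformation") {
      labels <- vapply(atoms, `[[`, character(1), "label")
      for (b in seq_len(nrow(bonds))) {
        ia_all <- which(labels == bonds$from[b])
        ib_all <- which(labels == bonds$to[b])
        if (length(ia_all) == 0 || length(ib_all) == 0)
          stop("deformation bond references unknown atom label")
        for (ia in ia_all) {
          xa <- atoms[[ia]]$frac_pos
          # nearest periodic image of the bond partner defines the direction
          best <- NULL; best_d <- Inf
          for (ib in ib_all) {
            d <- wrap_diff(atoms[[ib]]$frac_pos - xa)
            dc <- frac_to_cart(d, cell)
            dn <- sqrt(sum(dc^2))
            if (dn < best_d && dn > 1e-8) { best_d <- dn; best <- dc / dn }
          }
          vals <- vals + deformation_on_grid(cell, shape, xa, best,
                                             bonds$p[b], beta)
        }
      }
      if (min(vals) < -1e-3)
        warning(sprintf("deformation drives the valence density negative (min %.3g e/A^3)",
                        min(vals)))
    }
    list(grid = density_grid(vals, cell), per_atom_pro = pm$per_atom)
  }
  structure(list(kind = kind, bonds = bonds, p = p, beta = beta,
                 proatom = proatom, core = core, valence_grid = valence_grid),
            class = "density_source")
}

proatom_table <- function(atoms, proatom_fun) {
  els <- unique(vapply(atoms, `[[`, character(1), "element"))
  stats::setNames(lapply(els, proatom_fun), els)
}

# dipolar deformation density summed over periodic images
deformation_on_grid <- function(cell, shape, frac_pos, u_hat, p, beta,
                                cutoff_rho = 1e-10) {
  shape <- as.integer(shape)
  G <- metric_tensors(cell)$G
  A <- orthogonalization_matrix(cell)
  sigma_min <- min(svd(A)$d)
  ax <- grid_axis_arrays(shape)
  f1 <- axis_frac(shape[1]); f2 <- axis_frac(shape[2]); f3 <- axis_frac(shape[3])
  astar <- reciprocal_lengths(cell)
  # envelope |p| r exp(-beta r^2) < cutoff
  rs <- seq(0.1, 30, by = 0.05)
  env <- abs(p) * rs * exp(-beta * rs^2)
  r_cut <- rs[max(which(env >= cutoff_rho), 1)]
  m <- pmax(1L, as.integer(ceiling(r_cut * astar)))
  x <- frac_pos %% 1
  vals <- array(0, shape)
  # Cartesian components of the grid-to-atom vector via the orthogonalization
  for (s1 in -m[1]:m[1]) for (s2 in -m[2]:m[2]) for (s3 in -m[3]:m[3]) {
    sft <- c(s1, s2, s3)
    lo <- -x - sft; hi <- 1 - x - sft
    gap <- pmax(0, pmax(lo, -hi))
    if (sigma_min * sqrt(sum(gap^2)) > r_cut) next
    d1 <- f1 - x[1] - s1; d2 <- f2 - x[2] - s2; d3 <- f3 - x[3] - s3
    X1 <- ax$x1(d1); X2 <- ax$x2(d2); X3 <- ax$x3(d3)
    r2 <- G[1, 1] * X1^2 + G[2, 2] * X2^2 + G[3, 3] * X3^2 +
      2 * (G[1, 2] * X1 * X2 + G[1, 3] * X1 * X3 + G[2, 3] * X2 * X3)
    sel <- r2 <= r_cut^2
    if (!any(sel)) next
    # projection of the Cartesian offset onto the bond direction
    w <- as.numeric(t(u_hat) %*% A)  # (u . A d) = (t(u) A) . d_frac
    proj <- w[1] * X1[sel] + w[2] * X2[sel] + w[3] * X3[sel]
    vals[sel] <- vals[sel] + p * proj * exp(-beta * r2[sel])
  }
  vals
}

#' Closed-form centroid shift of the dipolar deformation
#'
#' First moment of \code{p (s.u) exp(-beta s^2)} divided by the atom's
#' valence electron count: the deformed atom's density centroid moves along
#' the bond by \code{p (pi/beta)^{3/2} / (2 beta) / n_valence} angstrom.
#'
#' @param p Deformation amplitude (e / angstrom^4).
#' @param beta Envelope exponent (angstrom^-2).
#' @param n_valence Valence electron count of the deformed atom.
#' @return Signed centroid shift in angstrom (positive towards the bond
#'   partner).
#' @export
deformation_centroid_shift <- function(p, beta, n_valence) {
  p * (pi / beta)^1.5 / (2 * beta) / n_valence
}

#' Aspherical form factors from a density source
#'
#' Runs the grid pipeline once at the current geometry: expand to P1, build
#' the promolecule, obtain the valence density from the source, Hirshfeld-
#' partition it, Fourier-transform each atomic grid (atom-centred), and add
#' the spherical frozen-core form factor from the Fourier-Bessel transform.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param source A \code{density_source}.
#' @param hkl Integer matrix (n x 3) of reflection indices.
#' @param spacing Grid spacing in angstrom (default 0.1); the grid shape is
#'   chosen per axis via \code{\link{grid_shape_for_spacing}}.
#' @param interp_factor Integer Fourier-interpolation factor applied to both
#'   the valence and pro-atom grids before partitioning (default 1).
#' @return List with \code{ff} (complex n_hkl x n_images matrix),
#'   \code{images} (the P1 expansion), \code{electron_counts} (partitioned
#'   valence electron count per image atom) and \code{core_counts}.
#' @export
ff_from_source <- function(structure, source, hkl, spacing = 0.1,
                           interp_factor = 1) {
  p1 <- expand_to_p1(structure)
  atoms <- lapply(p1, `[[`, "atom")
  cell <- structure$cell
  shape <- grid_shape_for_spacing(cell, spacing)
  vg <- source$valence_grid(atoms, shape, cell)
  valence <- vg$grid
  per_pro <- vg$per_atom_pro
  if (interp_factor > 1) {
    valence <- interpolate_grid(valence, interp_factor)
    per_pro <- lapply(per_pro, interpolate_grid, factor = interp_factor)
  }
  parts <- hirshfeld_partition(valence, per_pro)
  s <- resolution(hkl, cell)
  els <- unique(vapply(atoms, `[[`, character(1), "element"))
  core_ff <- stats::setNames(lapply(els, function(el)
    fourier_bessel_ff(source$core(el), s)), els)
  core_n <- stats::setNames(vapply(els, function(el)
    source$core(el)$n_electrons, numeric(1)), els)
  ff <- matrix(0 + 0i, nrow = nrow(hkl), ncol = length(atoms))
  for (i in seq_along(atoms)) {
    fv <- grid_form_factor(parts[[i]], atoms[[i]]$frac_pos, hkl)
    ff[, i] <- core_ff[[atoms[[i]]$element]] + fv
  }
  list(ff = ff, images = p1,
       electron_counts = vapply(parts, grid_integral, numeric(1)),
       core_counts = unname(core_n[vapply(atoms, `[[`, character(1), "element")]))
}

#' Spherical (IAM-style) form factors from a source's pro-atoms
#'
#' Independent-atom-model form factors: the Fourier-Bessel transform of each
#' element's spherical core + pro-atom valence density, identical for every
#' image of the element and real-valued.
#'
#' @inheritParams ff_from_source
#' @return Same contract as \code{\link{ff_from_source}}.
#' @export
ff_iam <- function(structure, source, hkl) {
  p1 <- expand_to_p1(structure)
  atoms <- lapply(p1, `[[`, "atom")
  s <- resolution(hkl, structure$cell)
  els <- unique(vapply(atoms, `[[`, character(1), "element"))
  tot_ff <- stats::setNames(lapply(els, function(el) {
    fourier_bessel_ff(source$core(el), s) +
      fourier_bessel_ff(source$proatom(el), s)
  }), els)
  val_n <- stats::setNames(vapply(els, function(el)
    source$proatom(el)$n_electrons, numeric(1)), els)
  ff <- matrix(0 + 0i, nrow = nrow(hkl), ncol = length(atoms))
  for (i in seq_along(atoms))
    ff[, i] <- tot_ff[[atoms[[i]]$element]]
  list(ff = ff, images = p1,
       electron_counts = unname(val_n[vapply(atoms, `[[`, character(1), "element")]),
       core_counts = vapply(atoms, function(a) {
         sh <- synthetic_element_shells(a$element)$core
         if (is.null(sh)) 0 else sum(sh$n)
       }, numeric(1)))
}
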