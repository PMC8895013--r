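#' Periodic density grid over the unit cell
#'
#' Scalar electron density (e / angstrom^3) sampled at the fractional points
#' (i/n1, j/n2, k/n3), i = 0..n1-1 etc. Periodicity is implied by index
#' arithmetic modulo the shape.
#'
#' @param values 3-d numeric array of density values.
#' @param cell A \code{\link{unit_cell}}.
#' @return Object of class \code{density_grid}.
#' @export
density_grid <- function(values, cell) {
  stopifnot(is.array(values), length(dim(values)) == 3, inherits(cell, "unit_cell"))
  structure(list(shape = dim(values), values = values, cell = cell),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("density grid %d x %d x %d, integral %.4f e\n",
              x$shape[1], x$shape[2], x$shape[3], grid_integral(x)))
  invisible(x)
}

#' Integral of a density grid over the cell
#'
#' Mean value times cell volume (the exact quadrature for the periodic
#' trapezoidal/DFT sampling).
#'
#' @param grid A \code{\link{density_grid}}.
#' @return Scalar electron count.
#' @export
grid_integral <- function(grid) {
  mean(grid$values) * grid$cell$volume
}

#' Grid shape for a target spacing
#'
#' Even point counts per axis such that the grid spacing is at most
#' \code{spacing} along each cell edge.
#'
#' @param cell A \code{\link{unit_cell}}.
#' @param spacing Target spacing in angstrom.
#' @return Integer length-3 vector.
#' @export
grid_shape_for_spacing <- function(cell, spacing) {
  stopifnot(spacing > 0)
  2L * as.integer(ceiling(c(cell$a, cell$b, cell$c) / (2 * spacing)))
}

# fractional axis coordinates i/n, i = 0..n-1
axis_frac <- function(n) (0:(n - 1)) / n

# broadcast per-axis vectors to the full grid
grid_axis_arrays <- function(shape) {
  n1 <- shape[1]; n2 <- shape[2]; n3 <- shape[3]
  list(
    x1 = function(v) array(rep(v, times = n2 * n3), shape),
    x2 = function(v) array(rep(rep(v, each = n1), times = n3), shape),
    x3 = function(v) array(rep(v, each = n1 * n2), shape)
  )
}

#' Promolecule density on a grid
#'
#' Sums spherical pro-atom densities over the atoms of a P1 atom list,
#' including all periodic images whose contribution exceeds the cutoff
#' density. Images are enumerated out to the radius where the radial density
#' drops below \code{cutoff_rho}.
#'
#' @param atoms List of \code{\link{atom}}s covering the unit cell (e.g. the
#'   \code{$atom} entries of \code{\link{expand_to_p1}} output).
#' @param pro_densities Named list mapping element symbols to
#'   \code{\link{spherical_density}} objects.
#' @param shape Integer length-3 grid shape.
#' @param cell A \code{\link{unit_cell}}.
#' @param cutoff_rho Lattice-sum image cutoff (e / angstrom^3, default 1e-10).
#' @return List with \code{total} (a \code{\link{density_grid}}) and
#'   \code{per_atom} (list of \code{density_grid}, one per input atom);
#'   the total equals the sum of the per-atom grids exactly.
#' @export
promolecule_on_grid <- function(atoms, pro_densities, shape, cell,
                                cutoff_rho = 1e-10) {
  shape <- as.integer(shape)
  G <- metric_tensors(cell)$G
  A <- orthogonalization_matrix(cell)
  sigma_min <- min(svd(A)$d)
  ax <- grid_axis_arrays(shape)
  f1 <- axis_frac(shape[1]); f2 <- axis_frac(shape[2]); f3 <- axis_frac(shape[3])
  astar <- reciprocal_lengths(cell)
  per_atom <- vector("list", length(atoms))
  for (ia in seq_along(atoms)) {
    at <- atoms[[ia]]
    sd <- pro_densities[[at$element]]
    if (is.null(sd)) stop("no pro-atom density for element ", at$element)
    above <- sd$rho >= cutoff_rho
    r_cut <- if (any(above)) max(sd$r[above]) else sd$r[1]
    m <- pmax(1L, as.integer(ceiling(r_cut * astar)))
    vals <- array(0, shape)
    x <- at$frac_pos %% 1
    for (s1 in -m[1]:m[1]) for (s2 in -m[2]:m[2]) for (s3 in -m[3]:m[3]) {
      sft <- c(s1, s2, s3)
      # rigorous prune: distance from the image to the grid box is at least
      # sigma_min(A) times the per-axis fractional gap norm
      lo <- -x - sft; hi <- 1 - x - sft
      gap <- pmax(0, pmax(lo, -hi))
      if (sigma_min * sqrt(sum(gap^2)) > r_cut) next
      d1 <- f1 - x[1] - s1; d2 <- f2 - x[2] - s2; d3 <- f3 - x[3] - s3
      X1 <- ax$x1(d1); X2 <- ax$x2(d2); X3 <- ax$x3(d3)
      r2 <- G[1, 1] * X1^2 + G[2, 2] * X2^2 + G[3, 3] * X3^2 +
        2 * (G[1, 2] * X1 * X2 + G[1, 3] * X1 * X3 + G[2, 3] * X2 * X3)
      sel <- r2 <= r_cut^2
      if (!any(sel)) next
      vals[sel] <- vals[sel] + at$occupancy * eval_spherical_density(sd, sqrt(r2[sel]))
    }
    per_atom[[ia]] <- density_grid(vals, cell)
  }
  total <- Reduce(`+`, lapply(per_atom, `[[`, "values"))
  list(total = density_grid(total, cell), per_atom = per_atom)
}

#' Hirshfeld stockholder partition of a density grid
#'
#' Distributes the valence density among atoms with stockholder weights
#' w_A = rho_A^pro / sum_B rho_B^pro pointwise. Points where the promolecule
#' falls below the floor \code{eps} contribute zero to every atom (the
#' density there is numerically zero anyway).
#'
#' @param valence A \code{\link{density_grid}} with the cell valence density.
#' @param per_atom_pro List of per-atom promolecule \code{density_grid}s
#'   sharing the valence grid's shape (from \code{\link{promolecule_on_grid}}).
#' @param eps Promolecule denominator floor (default 1e-30).
#' @return List of per-atom valence \code{\link{density_grid}}s; their sum
#'   reproduces the valence grid wherever the promolecule exceeds \code{eps}.
#' @export
hirshfeld_partition <- function(valence, per_atom_pro, eps = 1e-30) {
  for (g in per_atom_pro)
    if (!identical(g$shape, valence$shape))
      stop("promolecule and valence grids must share the same shape")
  denom <- Reduce(`+`, lapply(per_atom_pro, `[[`, "values"))
  ok <- denom > eps
  inv <- array(0, valence$shape)
  inv[ok] <- 1 / denom[ok]
  lapply(per_atom_pro, function(g)
    density_grid(g$values * inv * valence$values, valence$cell))
}

#' Atom-centred form factor from a density grid
#'
#' Discrete Fourier transform of an atomic density grid with the
#' crystallographic kernel exp(+2 pi i h.x), normalized by V/N, then phase
#' shifted by exp(-2 pi i h.x_atom) to give the atom-centred value. At
#' h = (0,0,0) this is the partitioned electron count of the atom.
#'
#' @param grid A \code{\link{density_grid}} holding one atom's density.
#' @param frac_pos The atom's fractional position (length 3).
#' @param hkl Integer matrix (n x 3) of reflection indices; every index must
#'   lie below the FFT Nyquist limit of the grid.
#' @return Complex vector of form-factor values, one per row of \code{hkl}.
#' @export
grid_form_factor <- function(grid, frac_pos, hkl) {
  hkl <- matrix(as.numeric(hkl), ncol = 3)
  n <- grid$shape
  lim <- (n - 1) %/% 2
  bad <- which(abs(hkl[, 1]) > lim[1] | abs(hkl[, 2]) > lim[2] | abs(hkl[, 3]) > lim[3])
  if (length(bad) > 0)
    stop(sprintf("hkl (%d %d %d) beyond the FFT Nyquist limit of the %d x %d x %d grid",
                 hkl[bad[1], 1], hkl[bad[1], 2], hkl[bad[1], 3], n[1], n[2], n[3]))
  Fg <- stats::fft(grid$values, inverse = TRUE) * grid$cell$volume / prod(n)
  idx <- cbind(hkl[, 1] %% n[1], hkl[, 2] %% n[2], hkl[, 3] %% n[3]) + 1
  Fg[idx] * exp(-2i * pi * as.numeric(hkl %*% frac_pos))
}

# spectral zero-padding expansion matrix for one axis (n_new >= n_old);
# an even old Nyquist bin is split half/half over +n/2 and -n/2
pad_expansion_matrix <- function(n_old, n_new) {
  stopifnot(n_new >= n_old)
  E <- matrix(0, n_new, n_old)
  for (k in 0:(n_old - 1)) {
    ks <- if (k <= n_old / 2) k else k - n_old
    if (n_old %% 2 == 0 && k == n_old / 2 && n_new > n_old) {
      E[(ks %% n_new) + 1, k + 1] <- 0.5
      E[((-ks) %% n_new) + 1, k + 1] <- E[((-ks) %% n_new) + 1, k + 1] + 0.5
    } else {
      E[(ks %% n_new) + 1, k + 1] <- 1
    }
  }
  E
}

apply_along_axis1 <- function(arr, M) {
  d <- dim(arr)
  out <- M %*% matrix(arr, d[1], d[2] * d[3])
  array(out, c(nrow(M), d[2], d[3]))
}

#' Fourier interpolation of a density grid
#'
#' Interpolates to an integer-factor finer grid by zero-padding the discrete
#' Fourier spectrum. The grid integral (DC term) is preserved exactly and
#' band-limited inputs are reproduced exactly at the new points.
#'
#' @param grid A \code{\link{density_grid}}.
#' @param factor Integer refinement factor >= 1 (1 returns the input).
#' @return A \code{\link{density_grid}} with shape \code{factor * shape}.
#' @export
interpolate_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) return(grid)
  n_old <- grid$shape
  n_new <- n_old * factor
  Y <- stats::fft(grid$values)
  Y <- apply_along_axis1(Y, pad_expansion_matrix(n_old[1], n_new[1]))
  Y <- aperm(Y, c(2, 3, 1))
  Y <- apply_along_axis1(Y, pad_expansion_matrix(n_old[2], n_new[2]))
  Y <- aperm(Y, c(2, 3, 1))
  Y <- apply_along_axis1(Y, pad_expansion_matrix(n_old[3], n_new[3]))
  Y <- aperm(Y, c(2, 3, 1))
  vals <- Re(stats::fft(Y, inverse = TRUE)) / prod(n_old)
  density_grid(vals, grid$cell)
}
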