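#' Exponential radial grid
#'
#' Strictly increasing abscissae r_i = r_min * (r_max/r_min)^(i/(n-1)).
#'
#' @param n Number of points (default 2^13 + 1; the transform converges well
#'   before the 2^19 + 1 used for production-grade core tables, which remains
#'   available through this argument).
#' @param r_min,r_max Grid range in angstrom.
#' @return Numeric vector of length \code{n}.
#' @export
radial_grid_exp <- function(n = 2^13 + 1, r_min = 1e-6, r_max = 30) {
  stopifnot(n >= 2, r_min > 0, r_max > r_min)
  r_min * (r_max / r_min)^(seq(0, 1, length.out = n))
}

#' Spherical atomic density on a radial grid
#'
#' @param r Strictly increasing radial abscissae (angstrom), usually an
#'   exponential grid from \code{\link{radial_grid_exp}}.
#' @param rho Density values (e / angstrom^3), non-negative.
#' @param n_electrons Nominal electron count represented by the density.
#' @param fun Optional closure \code{function(r)} evaluating the density at
#'   arbitrary radii (used by the grid promolecule builder; tabulated-only
#'   densities fall back to monotone interpolation).
#' @return Object of class \code{spherical_density}.
#' @export
spherical_density <- function(r, rho, n_electrons, fun = NULL) {
  stopifnot(length(r) == length(rho))
  if (any(diff(r) <= 0)) stop("radial grid must be strictly increasing")
  if (any(rho < -1e-12)) stop("spherical density must be non-negative")
  structure(list(r = r, rho = pmax(rho, 0), n_electrons = n_electrons, fun = fun),
            class = "spherical_density")
}

eval_spherical_density <- function(sd, r) {
  if (!is.null(sd$fun)) return(sd$fun(r))
  out <- numeric(length(r))
  inside <- r <= sd$r[length(sd$r)]
  f <- stats::splinefun(sd$r, sd$rho, method = "monoH.FC")
  out[inside] <- pmax(f(pmax(r[inside], sd$r[1])), 0)
  out
}

#' Radial quadrature of a spherical density
#'
#' 4 pi Int rho(r) r^2 dr on the radial grid. Exponential grids with an odd
#' point count (the default 2^13 + 1) are integrated by composite Simpson in
#' log r; any other strictly increasing grid falls back to the trapezoidal
#' rule.
#'
#' @param sd A \code{\link{spherical_density}}.
#' @return Scalar electron count.
#' @export
spherical_density_integral <- function(sd) {
  quad_radial(sd$r, 4 * pi * sd$r^2 * sd$rho)
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

# integral of y dr over a radial grid: composite Simpson in t = log r when
# the grid is log-uniform with an odd point count, trapezoid otherwise
quad_radial <- function(r, y) {
  n <- length(r)
  dt <- diff(log(r))
  if (n >= 3 && n %% 2 == 1 && max(abs(dt - dt[1])) < 1e-9 * dt[1]) {
    ft <- y * r  # dr = r dt
    h <- dt[1]
    idx_odd <- seq(2, n - 1, by = 2)
    idx_even <- seq(3, n - 2, by = 2)
    h / 3 * (ft[1] + ft[n] + 4 * sum(ft[idx_odd]) +
               if (length(idx_even) > 0) 2 * sum(ft[idx_even]) else 0)
  } else {
    trapz(r, y)
  }
}

#' Fourier-Bessel transform of a spherical density
#'
#' Spherical form factor
#' \deqn{f(s) = \int 4\pi r^2 \rho(r)\, \mathrm{sinc}(Q r)\, dr,\quad Q = 4\pi s,}
#' evaluated by composite Simpson quadrature in log r on the exponential
#' radial grid (trapezoidal fallback for non-uniform grids). At s = 0 this
#' is the electron count of the density.
#'
#' @param sd A \code{\link{spherical_density}}.
#' @param s_values Numeric vector of sin(theta)/lambda values (angstrom^-1),
#'   all >= 0.
#' @return Real form-factor values, one per \code{s}.
#' @examples
#' r <- radial_grid_exp()
#' zeta <- 1.89
#' sd <- spherical_density(r, zeta^3 / pi * exp(-2 * zeta * r), 1)
#' fourier_bessel_ff(sd, 0)  # 1 electron
#' @export
fourier_bessel_ff <- function(sd, s_values) {
  stopifnot(inherits(sd, "spherical_density"))
  if (any(s_values < 0)) stop("s values must be non-negative")
  r <- sd$r
  base <- 4 * pi * r^2 * sd$rho
  vapply(s_values, function(s) {
    if (s == 0) return(quad_radial(r, base))
    Q <- 4 * pi * s
    quad_radial(r, base * sin(Q * r) / (Q * r))
  }, numeric(1))
}

# ---- synthetic per-element radial densities --------------------------------
# Gaussian-shell mixtures with a core/valence split by shell. These are
# documented model constants for the self-contained density source, not
# physical reference data: H is all valence; C, N, O carry 2 core electrons
# in the tightest shell. rho(r) = sum n_s (alpha_s/pi)^(3/2) exp(-alpha_s r^2),
# alpha in angstrom^-2.
synthetic_element_shells <- function(element) {
  tab <- list(
    H = list(core = NULL,
             valence = list(n = 1.0, alpha = 2.0)),
    C = list(core = list(n = 2, alpha = 180),
             valence = list(n = c(2.4, 1.6), alpha = c(6.0, 1.5))),
    N = list(core = list(n = 2, alpha = 250),
             valence = list(n = c(3.0, 2.0), alpha = c(8.0, 2.0))),
    O = list(core = list(n = 2, alpha = 320),
             valence = list(n = c(3.6, 2.4), alpha = c(10.0, 2.5)))
  )
  sh <- tab[[element]]
  if (is.null(sh)) stop("no synthetic density for element ", element)
  sh
}

gaussian_mixture_density <- function(n, alpha) {
  force(n); force(alpha)
  function(r) {
    out <- 0
    for (s in seq_along(n))
      out <- out + n[s] * (alpha[s] / pi)^1.5 * exp(-alpha[s] * r^2)
    out
  }
}

#' Closed-form Gaussian-mixture form factor
#'
#' Analytic transform of \code{sum n_s (alpha_s/pi)^{3/2} exp(-alpha_s r^2)}:
#' \code{f(s) = sum n_s exp(-Q^2 / (4 alpha_s))} with Q = 4 pi s. Used as the
#' closed-form reference for the grid and radial-quadrature pathways.
#'
#' @param n,alpha Shell electron counts and exponents (angstrom^-2).
#' @param s_values sin(theta)/lambda values (angstrom^-1).
#' @return Real form-factor values.
#' @export
gaussian_mixture_ff <- function(n, alpha, s_values) {
  Q2 <- (4 * pi * s_values)^2
  out <- numeric(length(s_values))
  for (s in seq_along(n)) out <- out + n[s] * exp(-Q2 / (4 * alpha[s]))
  out
}

# spherical_density for a shell specification (core or valence of an element)
shell_spherical_density <- function(shell, grid = radial_grid_exp()) {
  if (is.null(shell)) {
    return(spherical_density(grid, numeric(length(grid)), 0, fun = function(r) 0 * r))
  }
  f <- gaussian_mixture_density(shell$n, shell$alpha)
  spherical_density(grid, f(grid), sum(shell$n), fun = f)
}
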