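#' Refinement settings
#'
#' @param max_lsq_cycles Cap on damped Gauss-Newton cycles of one
#'   least-squares refinement (default 200).
#' @param max_har_cycles Cap on outer density-update cycles of
#'   \code{\link{har_iterate}}; 0 requests the degenerate loop (an
#'   independent-atom-model refinement with the source's spherical
#'   pro-atoms).
#' @param shift_tol Convergence threshold on the largest absolute parameter
#'   shift within a least-squares refinement (fractional coordinates /
#'   angstrom^2; default 1e-6).
#' @param har_shift_tol Convergence threshold on the largest absolute
#'   parameter change between outer density cycles (default 1e-4).
#' @param refine_positions,refine_adp Parameter-class switches.
#' @param refine_extinction Refine the secondary-extinction parameter x
#'   (the weighting w = 1/sigma^2 is fixed, never refined).
#' @param gc3_atoms,gc4_atoms Character vectors of atom labels whose third-
#'   and fourth-order Gram-Charlier tensors are refined.
#' @param fsig_cutoff Significance threshold t on F/sigma(F) applied once
#'   before refinement (0 = keep all data).
#' @param fix_origin Project the floating-origin degeneracy out of the free
#'   parameters: along every polar direction of the space group (directions
#'   invariant under all rotations) the intensities are invariant under a
#'   common translation, so the summed positional shift along those
#'   directions is constrained to zero (default \code{TRUE}).
#' @param grid_spacing Density grid spacing for the form-factor pipeline
#'   (angstrom, default 0.1).
#' @param interp_factor Fourier-interpolation factor applied before
#'   partitioning (default 1).
#' @param seed Fixed seed for any stochastic utility (unused by the
#'   deterministic refiner itself).
#' @return List of class \code{refinement_settings}.
#' @export
refinement_settings <- function(max_lsq_cycles = 200, max_har_cycles = 10,
                                shift_tol = 1e-6, har_shift_tol = 1e-4,
                                refine_positions = TRUE, refine_adp = TRUE,
                                refine_extinction = FALSE,
                                gc3_atoms = character(0),
                                gc4_atoms = character(0),
                                fsig_cutoff = 0, fix_origin = TRUE,
                                grid_spacing = 0.1, interp_factor = 1,
                                seed = NULL) {
  stopifnot(shift_tol > 0, har_shift_tol > 0, max_lsq_cycles >= 1,
            max_har_cycles >= 0, fsig_cutoff >= 0)
  structure(list(max_lsq_cycles = max_lsq_cycles,
                 max_har_cycles = max_har_cycles,
                 shift_tol = shift_tol, har_shift_tol = har_shift_tol,
                 refine_positions = refine_positions, refine_adp = refine_adp,
                 refine_extinction = refine_extinction,
                 gc3_atoms = gc3_atoms, gc4_atoms = gc4_atoms,
                 fsig_cutoff = fsig_cutoff, fix_origin = fix_origin,
                 grid_spacing = grid_spacing, interp_factor = interp_factor,
                 seed = seed),
            class = "refinement_settings")
}

# ---- constrained parameter map ---------------------------------------------
# Free parameters are mapped to full model parameters through the linear
# reparameterization full = offset + basis %*% free generated by
# site_constraints, which keeps parameter counts honest on special positions.
build_param_map <- function(structure, settings) {
  blocks <- list()
  p0 <- numeric(0)
  for (ia in seq_along(structure$atoms)) {
    at <- structure$atoms[[ia]]
    cons <- site_constraints(at, structure$symmetry)
    if (settings$refine_positions) {
      B <- cons$pos$basis
      x0 <- cons$pos$offset
      init <- as.numeric(crossprod(B, at$frac_pos - x0))
      blocks[[length(blocks) + 1]] <- list(kind = "pos", atom = ia, basis = B,
                                           offset = x0,
                                           idx = length(p0) + seq_len(ncol(B)))
      p0 <- c(p0, init)
    }
    if (settings$refine_adp) {
      if (!is.null(at$uaniso)) {
        B <- cons$u6
        init <- as.numeric(crossprod(B, at$uaniso))
        blocks[[length(blocks) + 1]] <- list(kind = "uaniso", atom = ia, basis = B,
                                             idx = length(p0) + seq_len(ncol(B)))
        p0 <- c(p0, init)
      } else {
        blocks[[length(blocks) + 1]] <- list(kind = "uiso", atom = ia,
                                             idx = length(p0) + 1L)
        p0 <- c(p0, at$uiso)
      }
    }
    if (at$label %in% settings$gc3_atoms) {
      B <- cons$gc3
      cur <- if (is.null(at$gc3)) numeric(10) else at$gc3
      blocks[[length(blocks) + 1]] <- list(kind = "gc3", atom = ia, basis = B,
                                           idx = length(p0) + seq_len(ncol(B)))
      p0 <- c(p0, as.numeric(crossprod(B, cur)))
    }
    if (at$label %in% settings$gc4_atoms) {
      B <- cons$gc4
      cur <- if (is.null(at$gc4)) numeric(15) else at$gc4
      blocks[[length(blocks) + 1]] <- list(kind = "gc4", atom = ia, basis = B,
                                           idx = length(p0) + seq_len(ncol(B)))
      p0 <- c(p0, as.numeric(crossprod(B, cur)))
    }
  }
  if (settings$refine_extinction) {
    blocks[[length(blocks) + 1]] <- list(kind = "ext", idx = length(p0) + 1L)
    p0 <- c(p0, 0)
  }
  list(blocks = blocks, p0 = p0)
}

# rebuild the structure (and extinction parameter) from free parameters
apply_param_map <- function(structure, pmap, p) {
  ext <- 0
  for (bl in pmap$blocks) {
    v <- p[bl$idx]
    switch(bl$kind,
      pos = {
        structure$atoms[[bl$atom]]$frac_pos <-
          bl$offset + as.numeric(bl$basis %*% v)
      },
      uaniso = {
        structure$atoms[[bl$atom]]$uaniso <- as.numeric(bl$basis %*% v)
      },
      uiso = {
        structure$atoms[[bl$atom]]$uiso <- v
      },
      gc3 = {
        structure$atoms[[bl$atom]]$gc3 <- as.numeric(bl$basis %*% v)
      },
      gc4 = {
        structure$atoms[[bl$atom]]$gc4 <- as.numeric(bl$basis %*% v)
      },
      ext = {
        ext <- v
      })
  }
  list(structure = structure, extinction = ext)
}

#' Refinement objective with analytic gradient
#'
#' Builds the weighted least-squares problem
#' \code{SS(p) = sum w (Fo^2 - k I(p))^2}, w = 1/sigma^2, where I is the
#' (optionally extinction-corrected) model intensity and the scale k is
#' eliminated by its closed-form minimizer at every evaluation (so the
#' gradient at fixed k is the total gradient, by the envelope theorem).
#' Exposed so the gradient can be validated against finite differences.
#'
#' @param structure Starting \code{\link{crystal_structure}}.
#' @param rs A \code{\link{reflection_set}} (already significance-filtered).
#' @param ff Complex n_hkl x n_images form-factor matrix.
#' @param images P1 expansion matching \code{ff}.
#' @param settings A \code{\link{refinement_settings}}.
#' @return List with \code{fn(p)} (objective), \code{gr(p)} (analytic
#'   gradient), \code{eval(p)} (full evaluation: SS, gradient, wR2, k,
#'   extinction, Fc, I), \code{p0} (starting free parameters) and
#'   \code{pmap}.
#' @export
refinement_problem <- function(structure, rs, ff, images, settings) {
  pmap <- build_param_map(structure, settings)
  hkl <- matrix(as.numeric(rs$hkl), ncol = 3)
  nh <- nrow(hkl)
  w <- 1 / rs$sigma^2
  fo2 <- rs$fo2
  cell <- structure$cell
  astar <- reciprocal_lengths(cell)
  s2 <- resolution(hkl, cell)^2
  lam <- rs$wavelength
  c0 <- extinction_coef(hkl, lam, cell, 1)  # coefficient for x = 1
  n_img <- length(images)
  hp_list <- lapply(images, function(rec) hkl %*% rec$op$R)
  u6p <- u6_pairs()
  u6mult <- c(1, 1, 1, 2, 2, 2)
  tab3 <- gc3_index_table(); tab4 <- gc4_index_table()

  evaluate <- function(p, need_grad = TRUE) {
    ap <- apply_param_map(structure, pmap, p)
    st <- ap$structure
    x_ext <- ap$extinction
    fc <- rep(0 + 0i, nh)
    contribs <- vector("list", n_img)
    contribs_nogc <- vector("list", n_img)
    for (im in seq_len(n_img)) {
      rec <- images[[im]]
      gen <- st$atoms[[rec$gen]]
      hp <- hp_list[[im]]
      pos <- as.numeric(rec$op$R %*% gen$frac_pos) + rec$op$t
      phase <- exp(2i * pi * as.numeric(hkl %*% pos))
      if (!is.null(gen$uaniso)) {
        M <- dw_quadratic_matrix(gen$uaniso, cell)
        Tdw <- exp(-2 * pi^2 * rowSums((hp %*% M) * hp))
      } else {
        Tdw <- exp(-8 * pi^2 * gen$uiso * s2)
      }
      base <- gen$occupancy * ff[, im] * Tdw * phase
      has_gc <- !is.null(gen$gc3) || !is.null(gen$gc4)
      if (has_gc) {
        gc <- gram_charlier(hp, gen$gc3, gen$gc4)
        contribs_nogc[[im]] <- base
        base <- base * gc
      }
      contribs[[im]] <- base
      fc <- fc + base
    }
    if (any(!is.finite(Re(fc))))
      stop("non-finite structure factors during refinement")
    fc2 <- Re(fc)^2 + Im(fc)^2
    cx <- c0 * x_ext
    root <- sqrt(1 + cx * fc2)
    I <- fc2 / root
    k <- optimal_scale(fo2, rs$sigma, I)
    resid <- fo2 - k * I
    SS <- sum(w * resid^2)
    wr2v <- sqrt(SS / sum(w * fo2^2))
    out <- list(f = SS, wr2 = wr2v, k = k, extinction = x_ext, fc = fc, I = I,
                structure = st)
    if (!need_grad) return(out)

    # analytic Jacobian of the weighted residuals r = sqrt(w) (Fo2 - k I),
    # including the closed-form scale's dependence on the parameters:
    # dr/dtheta = -sqrt(w) (k dI/dtheta + I dk/dtheta)
    sqrtw <- sqrt(w)
    rvec <- sqrtw * resid
    dI_dfc2 <- (1 + cx * fc2 / 2) / root^3
    dI_mat <- matrix(0, nh, length(p))
    for (bl in pmap$blocks) {
      if (bl$kind == "ext") {
        dI_dx <- -0.5 * fc2^2 * c0 / root^3
        dI_mat[, bl$idx] <- dI_dx
        next
      }
      ia <- bl$atom
      imgs <- which(vapply(images, function(r) r$gen == ia, logical(1)))
      nfull <- switch(bl$kind, pos = 3L, uaniso = 6L, uiso = 1L,
                      gc3 = 10L, gc4 = 15L)
      dFC <- matrix(0 + 0i, nh, nfull)
      for (im in imgs) {
        hp <- hp_list[[im]]
        cb <- contribs[[im]]
        if (bl$kind == "pos") {
          for (m in 1:3)
            dFC[, m] <- dFC[, m] + cb * (2i * pi * hp[, m])
        } else if (bl$kind == "uaniso") {
          for (cmp in 1:6) {
            i <- u6p[cmp, 1]; j <- u6p[cmp, 2]
            dlnT <- -2 * pi^2 * u6mult[cmp] * astar[i] * astar[j] *
              hp[, i] * hp[, j]
            dFC[, cmp] <- dFC[, cmp] + cb * dlnT
          }
        } else if (bl$kind == "uiso") {
          dFC[, 1] <- dFC[, 1] + cb * (-8 * pi^2 * s2)
        } else if (bl$kind == "gc3") {
          cb0 <- contribs_nogc[[im]]
          for (r in seq_len(nrow(tab3$idx))) {
            ix <- tab3$idx[r, ]
            dFC[, r] <- dFC[, r] + cb0 * ((2i * pi)^3 / 6 * tab3$mult[r] *
              hp[, ix[1]] * hp[, ix[2]] * hp[, ix[3]])
          }
        } else if (bl$kind == "gc4") {
          cb0 <- contribs_nogc[[im]]
          for (r in seq_len(nrow(tab4$idx))) {
            ix <- tab4$idx[r, ]
            dFC[, r] <- dFC[, r] + cb0 * ((2i * pi)^4 / 24 * tab4$mult[r] *
              hp[, ix[1]] * hp[, ix[2]] * hp[, ix[3]] * hp[, ix[4]])
          }
        }
      }
      dI_blk <- dI_dfc2 * (2 * Re(Conj(fc) * dFC))
      dI_mat[, bl$idx] <- if (bl$kind == "uiso") dI_blk else dI_blk %*% bl$basis
    }
    dk <- as.numeric(crossprod(dI_mat, w * (fo2 - 2 * k * I))) /
      sum(w * I^2)
    J <- -sqrtw * (k * dI_mat + outer(I, dk))
    out$r <- rvec
    out$J <- J
    out$g <- as.numeric(2 * crossprod(J, rvec))
    out
  }

  # optional origin fixing: restrict the free parameters to the null space
  # of the summed positional shift along the polar directions of the group
  n_par <- length(pmap$p0)
  Z <- diag(nrow = n_par)
  if (isTRUE(settings$fix_origin) && n_par > 0) {
    polar <- invariant_basis(lapply(structure$symmetry, function(op) op$R))
    if (ncol(polar) > 0) {
      V <- NULL
      for (d in seq_len(ncol(polar))) {
        v <- numeric(n_par)
        for (bl in pmap$blocks) if (bl$kind == "pos")
          v[bl$idx] <- as.numeric(crossprod(bl$basis, polar[, d]))
        V <- rbind(V, v)
      }
      V <- V[rowSums(abs(V)) > 1e-12, , drop = FALSE]
      if (!is.null(V) && nrow(V) > 0) {
        qrv <- qr(t(V))
        r <- qrv$rank
        if (r < n_par)
          Z <- qr.Q(qrv, complete = TRUE)[, seq.int(r + 1, n_par), drop = FALSE]
      }
    }
  }
  eval_q <- function(q, need_grad = TRUE) {
    out <- evaluate(pmap$p0 + as.numeric(Z %*% q), need_grad)
    if (need_grad) {
      out$g <- as.numeric(crossprod(Z, out$g))
      out$J <- out$J %*% Z
    }
    out
  }
  list(fn = function(q) eval_q(q, need_grad = FALSE)$f,
       gr = function(q) eval_q(q, need_grad = TRUE)$g,
       eval = eval_q, p0 = numeric(ncol(Z)), pmap = pmap, Z = Z,
       p_base = pmap$p0)
}

# ---- damped Gauss-Newton (Levenberg-Marquardt) -----------------------------
# Full-matrix least squares on the analytic Jacobian: solve
# (J'J + lambda diag(J'J)) delta = -J'r, accept only decreasing steps,
# declare convergence on the largest absolute parameter shift of an
# accepted step (the crystallographic convention). The objective history
# over accepted cycles is non-increasing by construction.
lm_minimize <- function(evaluate, p0, max_iter = 200, shift_tol = 1e-6) {
  n <- length(p0)
  p <- p0
  ev <- evaluate(p)
  f_hist <- ev$f
  wr2_hist <- ev$wr2
  shift_hist <- numeric(0)
  if (n == 0) {
    return(list(p = p, eval = ev, converged = TRUE, n_iter = 0,
                f_history = f_hist, wr2_history = wr2_hist,
                shift_history = shift_hist))
  }
  lambda <- 1e-4
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- crossprod(ev$J)
    g <- as.numeric(crossprod(ev$J, ev$r))
    dA <- pmax(diag(A), 1e-12 * max(diag(A), 1e-300))
    accepted <- FALSE
    for (tries in 1:40) {
      M <- A + lambda * diag(dA, n)
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (!is.null(delta)) {
        ev_new <- tryCatch(evaluate(p + delta), error = function(e) NULL)
        if (!is.null(ev_new) && is.finite(ev_new$f) && ev_new$f <= ev$f) {
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) { converged <- TRUE; break }  # no decreasing step exists
    p <- p + delta
    ev <- ev_new
    lambda <- max(lambda / 3, 1e-12)
    f_hist <- c(f_hist, ev$f)
    wr2_hist <- c(wr2_hist, ev$wr2)
    shift <- max(abs(delta))
    shift_hist <- c(shift_hist, shift)
    if (shift < shift_tol) { converged <- TRUE; break }
  }
  list(p = p, eval = ev, converged = converged, n_iter = length(shift_hist),
       f_history = f_hist, wr2_history = wr2_hist, shift_history = shift_hist)
}

#' Constrained least-squares refinement
#'
#' Minimizes \code{sum w (Fo^2 - k I)^2} (the argmin of wR2) over the free
#' parameters — positions, displacement parameters, optional Gram-Charlier
#' tensors and optional extinction — with the scale k eliminated in closed
#' form at every evaluation. The minimizer is full-matrix damped
#' Gauss-Newton (Levenberg-Marquardt) on the analytic Jacobian; convergence
#' is declared when the largest absolute parameter shift of an accepted
#' cycle falls below the tolerance. Form factors are held fixed throughout
#' (they are refreshed per outer cycle by \code{\link{har_iterate}}); the
#' atom-centring phases follow the refined positions. Special-position
#' constraints are applied as linear reparameterizations.
#'
#' @inheritParams refinement_problem
#' @return Object of class \code{refinement_result}: the refined
#'   \code{structure}, \code{scale}, \code{extinction}, \code{wr2},
#'   \code{wr2_history} (per accepted cycle, non-increasing),
#'   \code{shift_history}, \code{converged}, \code{fc} and \code{n_par}.
#' @export
refine_lsq <- function(structure, rs, ff, images, settings = refinement_settings()) {
  prob <- refinement_problem(structure, rs, ff, images, settings)
  opt <- lm_minimize(function(p) prob$eval(p, need_grad = TRUE),
                     prob$p0,
                     max_iter = settings$max_lsq_cycles,
                     shift_tol = settings$shift_tol)
  ev <- opt$eval
  res <- list(structure = ev$structure, scale = ev$k,
              extinction = ev$extinction,
              wr2 = ev$wr2, wr2_history = opt$wr2_history,
              f_history = opt$f_history,
              shift_history = opt$shift_history,
              converged = opt$converged, n_cycles = opt$n_iter,
              fc = ev$fc, intensities = ev$I,
              n_par = length(prob$p0), settings = settings)
  class(res) <- "refinement_result"
  res
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("refinement: wR2 = %.4f%%, k = %.5g, %d free parameter(s), %d cycle(s)%s\n",
              100 * x$wr2, x$scale, x$n_par, x$n_cycles,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (x$extinction != 0) cat(sprintf("  extinction x = %.5g\n", x$extinction))
  invisible(x)
}

#' Iterative Hirshfeld atom refinement
#'
#' Outer loop of the method: recompute the density and the Hirshfeld-
#' partitioned aspherical form factors at the current geometry, run a full
#' least-squares refinement against them, and repeat until the largest
#' parameter change between density updates falls below
#' \code{har_shift_tol}. With \code{max_har_cycles = 0} the source's
#' spherical pro-atom form factors are used instead (an independent-atom-
#' model refinement).
#'
#' @param structure Starting \code{\link{crystal_structure}}.
#' @param rs A \code{\link{reflection_set}}.
#' @param source A \code{\link{synthetic_density_source}} (or any object
#'   honouring the density-source contract).
#' @param settings A \code{\link{refinement_settings}}.
#' @return The final \code{refinement_result} augmented with
#'   \code{har_cycles}, \code{har_wr2} (wR2 after each outer cycle),
#'   \code{har_shifts} (max parameter change between cycles) and
#'   \code{har_converged}.
#' @export
har_iterate <- function(structure, rs, source, settings = refinement_settings()) {
  if (settings$fsig_cutoff > 0)
    rs <- filter_significance(rs, settings$fsig_cutoff)
  hkl <- rs$hkl
  if (settings$max_har_cycles == 0) {
    ffr <- ff_iam(structure, source, hkl)
    res <- refine_lsq(structure, rs, ffr$ff, ffr$images, settings)
    res$har_cycles <- 0L
    res$har_wr2 <- res$wr2
    res$har_shifts <- numeric(0)
    res$har_converged <- res$converged
    return(res)
  }
  har_wr2 <- numeric(0)
  har_shifts <- numeric(0)
  res <- NULL
  har_converged <- FALSE
  for (cyc in seq_len(settings$max_har_cycles)) {
    ffr <- ff_from_source(structure, source, hkl,
                          spacing = settings$grid_spacing,
                          interp_factor = settings$interp_factor)
    res <- refine_lsq(structure, rs, ffr$ff, ffr$images, settings)
    shift <- max_structure_shift(structure, res$structure)
    structure <- res$structure
    har_wr2 <- c(har_wr2, res$wr2)
    har_shifts <- c(har_shifts, shift)
    if (shift < settings$har_shift_tol) { har_converged <- TRUE; break }
    nc <- length(har_shifts)
    if (nc >= 3 && har_shifts[nc] > har_shifts[nc - 1] &&
        har_shifts[nc - 1] > har_shifts[nc - 2]) {
      warning("outer HAR loop oscillates (parameter shifts increasing over 3 cycles)")
      break
    }
  }
  res$har_cycles <- length(har_shifts)
  res$har_wr2 <- har_wr2
  res$har_shifts <- har_shifts
  res$har_converged <- har_converged
  res
}

# largest absolute parameter change between two parameter states of the
# same model (wrapped fractional coordinates, U components, GC components)
max_structure_shift <- function(a, b) {
  m <- 0
  for (i in seq_along(a$atoms)) {
    at_a <- a$atoms[[i]]; at_b <- b$atoms[[i]]
    m <- max(m, abs(wrap_diff(at_a$frac_pos - at_b$frac_pos)))
    if (!is.null(at_a$uaniso) && !is.null(at_b$uaniso))
      m <- max(m, abs(at_a$uaniso - at_b$uaniso))
    else
      m <- max(m, abs(at_a$uiso - at_b$uiso))
    for (fld in c("gc3", "gc4")) {
      va <- at_a[[fld]]; vb <- at_b[[fld]]
      if (!is.null(va) || !is.null(vb)) {
        if (is.null(va)) va <- 0 * vb
        if (is.null(vb)) vb <- 0 * va
        m <- max(m, abs(va - vb))
      }
    }
  }
  m
}
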