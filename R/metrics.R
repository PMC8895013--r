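#' Blessing scaling of neutron displacement parameters
#'
#' Differences in measurement temperature, absorption and extinction between
#' the X-ray and neutron experiments are absorbed by fitting
#' \code{U_xray ~ q * U_neutron + DeltaU} over the paired non-H atoms in the
#' Cartesian frame: a single dimensionless scale q and one shared symmetric
#' additive offset DeltaU (angstrom^2), determined by linear least squares
#' on all nine tensor components (off-diagonals counted twice, i.e. the
#' Frobenius norm).
#'
#' @param u_xray List of symmetric 3x3 Cartesian displacement matrices from
#'   the X-ray refinement (non-H atoms).
#' @param u_neutron Matching list from the neutron reference.
#' @return Object of class \code{adp_scaling_fit} with \code{q},
#'   \code{delta_u} (symmetric 3x3), \code{residual_rms} and
#'   \code{correct(u)} — a closure returning the corrected neutron matrix
#'   \code{q * u + delta_u} for any atom (including H).
#' @export
scale_neutron_adps <- function(u_xray, u_neutron) {
  stopifnot(length(u_xray) == length(u_neutron))
  if (length(u_xray) < 2)
    stop("ADP scaling is under-determined: need at least 2 paired non-H atoms (7 unknowns)")
  wts <- c(1, 1, 1, 2, 2, 2)  # Frobenius weights for the 6 unique components
  X <- NULL; y <- NULL
  for (i in seq_along(u_xray)) {
    ux <- matrix_to_u6(u_xray[[i]])
    un <- matrix_to_u6(u_neutron[[i]])
    sw <- sqrt(wts)
    # rows: sw * (ux_c - q un_c - d_c) -> design over theta = (q, d1..d6)
    A <- cbind(sw * un, diag(sw))
    X <- rbind(X, A)
    y <- c(y, sw * ux)
  }
  theta <- qr.solve(X, y)
  q <- theta[1]
  du <- u6_to_matrix(theta[2:7])
  resid <- y - as.numeric(X %*% theta)
  fit <- list(q = q, delta_u = du,
              residual_rms = sqrt(mean(resid^2)),
              correct = function(u) q * u + du)
  class(fit) <- "adp_scaling_fit"
  fit
}

#' @export
print.adp_scaling_fit <- function(x, ...) {
  cat(sprintf("ADP scaling: q = %.5f, rms residual = %.3g A^2\n",
              x$q, x$residual_rms))
  invisible(x)
}

#' Bond-length differences between two structure models
#'
#' Signed differences \code{r_a - r_b} for a list of bonds, each distance
#' evaluated in its own structure's metric (nearest periodic image).
#'
#' @param structure_a,structure_b \code{\link{crystal_structure}} objects
#'   with matching atom labels.
#' @param bonds Data frame with character columns \code{from} and \code{to}.
#' @return Data frame with \code{from}, \code{to}, \code{r_a}, \code{r_b},
#'   \code{delta_r} and \code{abs_delta_r} (angstrom).
#' @export
delta_r <- function(structure_a, structure_b, bonds) {
  n <- nrow(bonds)
  ra <- rb <- numeric(n)
  for (i in seq_len(n)) {
    ra[i] <- bond_length(structure_a, bonds$from[i], bonds$to[i])
    rb[i] <- bond_length(structure_b, bonds$from[i], bonds$to[i])
  }
  data.frame(from = bonds$from, to = bonds$to, r_a = ra, r_b = rb,
             delta_r = ra - rb, abs_delta_r = abs(ra - rb))
}

bond_length <- function(structure, label1, label2) {
  a1 <- get_atom(structure, label1)
  a2 <- get_atom(structure, label2)
  G <- metric_tensors(structure$cell)$G
  d <- wrap_diff(a1$frac_pos - a2$frac_pos)
  sqrt(as.numeric(t(d) %*% G %*% d))
}

#' Displacement-ellipsoid similarity index S12
#'
#' Percent dissimilarity of the trivariate Gaussian probability densities
#' described by two displacement matrices (Cartesian convention):
#' \deqn{S_{12} = 100\,\Big[1 - 2^{3/2}
#'   \frac{(\det U_1^{-1} \det U_2^{-1})^{1/4}}
#'        {\det(U_1^{-1} + U_2^{-1})^{1/2}}\Big].}
#' Symmetric in its arguments, zero iff the matrices are equal, and
#' invariant under a common rotation.
#'
#' @param u1,u2 Symmetric positive definite 3x3 matrices (angstrom^2).
#' @return Scalar S12 in percent.
#' @export
s12 <- function(u1, u2) {
  for (u in list(u1, u2)) {
    ev <- eigen((u + t(u)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("S12 requires positive definite displacement matrices")
  }
  m1 <- solve(u1); m2 <- solve(u2)
  100 * (1 - 2^1.5 * (det(m1) * det(m2))^0.25 / sqrt(det(m1 + m2)))
}

#' Classify hydrogen atoms by bonding motif
#'
#' Assigns every H atom of the P1-expanded structure to one of the classes
#' \code{"C-H"}, \code{"intra X-H...Y"}, \code{"inter X-H...Y"} or
#' \code{"other X-H"} (covalently bound to N/O but with no acceptor in
#' range). A hydrogen bond follows the narrow classical criterion: donor X
#' and acceptor Y are N or O, H...Y below the distance cutoff and X-H...Y
#' above the angle cutoff. The geometric cutoffs are configurable (they are
#' a convention, not a measurement). H atoms with no covalent partner within
#' 1.3 angstrom are excluded with a warning.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param fragments Optional named character/integer vector mapping atom
#'   labels to fragment identifiers; hydrogen bonds within one fragment are
#'   "intra", across fragments "inter". Default: one fragment (all intra).
#' @param hb_max_dist H...Y cutoff in angstrom (default 2.5).
#' @param hb_min_angle X-H...Y cutoff in degrees (default 120).
#' @param covalent_max Covalent X-H search radius (default 1.3 angstrom).
#' @return Data frame with \code{h_label}, \code{donor}, \code{acceptor}
#'   (NA if none) and \code{class}.
#' @export
classify_bonds <- function(structure, fragments = NULL,
                           hb_max_dist = 2.5, hb_min_angle = 120,
                           covalent_max = 1.3) {
  p1 <- expand_to_p1(structure)
  atoms <- lapply(p1, `[[`, "atom")
  els <- vapply(atoms, `[[`, character(1), "element")
  labs <- vapply(atoms, `[[`, character(1), "label")
  cell <- structure$cell
  A <- orthogonalization_matrix(cell)
  pos <- t(vapply(atoms, `[[`, numeric(3), "frac_pos"))
  frag_of <- function(lab) {
    if (is.null(fragments)) 1 else fragments[[lab]]
  }
  # periodic pair vector (nearest image), Cartesian
  pair_vec <- function(i, j) as.numeric(A %*% wrap_diff(pos[j, ] - pos[i, ]))
  out <- NULL
  for (ih in which(els == "H")) {
    dists <- vapply(seq_along(atoms), function(j) {
      if (j == ih || els[j] == "H") return(Inf)
      sqrt(sum(pair_vec(ih, j)^2))
    }, numeric(1))
    jx <- which.min(dists)
    if (!is.finite(dists[jx]) || dists[jx] > covalent_max) {
      warning(sprintf("H atom %s has no covalent partner within %.2f A; excluded",
                      labs[ih], covalent_max))
      next
    }
    donor <- labs[jx]
    donor_el <- els[jx]
    cls <- NULL; acceptor <- NA_character_
    if (donor_el == "C") {
      cls <- "C-H"
    } else if (donor_el %in% c("N", "O")) {
      # search acceptors Y in N, O (excluding the donor image itself)
      best <- Inf; best_j <- NA
      for (j in which(els %in% c("N", "O"))) {
        if (j == jx) next
        vy <- pair_vec(ih, j)
        dy <- sqrt(sum(vy^2))
        if (dy >= hb_max_dist || dy < 1e-6) next
        vx <- pair_vec(ih, jx)
        ang <- acos(sum(vx * vy) / (sqrt(sum(vx^2)) * dy)) * 180 / pi
        if (ang <= hb_min_angle) next
        if (dy < best) { best <- dy; best_j <- j }
      }
      if (is.na(best_j)) {
        cls <- "other X-H"
      } else {
        acceptor <- labs[best_j]
        cls <- if (identical(frag_of(donor), frag_of(acceptor)))
          "intra X-H...Y" else "inter X-H...Y"
      }
    } else {
      cls <- "other X-H"
    }
    out <- rbind(out, data.frame(h_label = labs[ih], donor = donor,
                                 acceptor = acceptor, class = cls))
  }
  unique(out)
}

# inclusive five-number summary with 1.5 IQR whiskers; quartiles use the
# median-unbiased convention (quantile type 8)
box_summary <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0)
    return(list(n = 0, median = NA, q1 = NA, q3 = NA,
                whisker_low = NA, whisker_high = NA, mean_abs = NA))
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 8, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- v[v >= q[1] - 1.5 * iqr]
  hi <- v[v <= q[3] + 1.5 * iqr]
  list(n = length(v), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(lo), whisker_high = max(hi),
       mean_abs = mean(abs(v)))
}

#' Hydrogen-atom quality report against a neutron reference
#'
#' Assembles the quality indicators used to judge a refinement: wR2, signed
#' and absolute X-H bond-length differences to the reference, differences of
#' the H-atom displacement components against the Blessing-corrected
#' neutron values (Cartesian frame), the S12 ellipsoid similarity per H
#' atom, and per-bond-class summaries (median, quartiles, 1.5 IQR whiskers,
#' mean sigma-scaled absolute deviation).
#'
#' @param refined The refined \code{\link{crystal_structure}}.
#' @param neutron_ref The reference \code{\link{crystal_structure}} (same
#'   labels).
#' @param wr2 Optional wR2 of the refinement (carried through).
#' @param fragments Optional fragment map for \code{\link{classify_bonds}}.
#' @param sigma_r Mean standard uncertainty of the reference bond lengths
#'   (angstrom; scales Δr, default 1 = unscaled).
#' @param sigma_u Mean standard uncertainty of the reference displacement
#'   components (angstrom^2; scales ΔU, default 1 = unscaled).
#' @return Object of class \code{quality_report} (also serializable with
#'   \code{\link{write_quality_report}}).
#' @export
quality_report <- function(refined, neutron_ref, wr2 = NA_real_,
                           fragments = NULL, sigma_r = 1, sigma_u = 1) {
  classes <- classify_bonds(refined, fragments)
  bonds <- data.frame(from = classes$h_label, to = classes$donor)
  dr <- delta_r(refined, neutron_ref, bonds)
  dr$class <- classes$class
  # Blessing fit on non-H atoms, then corrected neutron U for H atoms
  labs_ref <- structure_labels(refined)
  is_h <- vapply(refined$atoms, function(a) a$element == "H", logical(1))
  ucart <- function(st, lab) {
    a <- get_atom(st, lab)
    if (is.null(a$uaniso)) diag(rep(a$uiso, 3)) else u_cif_to_cart(a$uaniso, st$cell)
  }
  nonh <- labs_ref[!is_h]
  if (length(nonh) >= 2) {
    fit <- scale_neutron_adps(lapply(nonh, ucart, st = refined),
                              lapply(nonh, ucart, st = neutron_ref))
  } else {
    warning("fewer than 2 non-H atoms: neutron ADPs compared unscaled (q = 1)")
    fit <- list(q = 1, delta_u = matrix(0, 3, 3), residual_rms = NA_real_,
                correct = function(u) u)
  }
  hlabs <- labs_ref[is_h]
  du_rows <- NULL
  s12_vals <- stats::setNames(numeric(0), character(0))
  for (hl in hlabs) {
    ux <- ucart(refined, hl)
    un <- fit$correct(ucart(neutron_ref, hl))
    d6 <- matrix_to_u6(ux - un)
    du_rows <- rbind(du_rows,
                     data.frame(h_label = hl,
                                component = c("U11", "U22", "U33", "U12", "U13", "U23"),
                                delta_u = d6, abs_delta_u = abs(d6)))
    s12_vals[hl] <- tryCatch(s12(ux, un), error = function(e) NA_real_)
  }
  cls_of_h <- stats::setNames(classes$class, classes$h_label)
  du_rows$class <- unname(cls_of_h[du_rows$h_label])
  per_class <- lapply(split(dr, dr$class), function(d) {
    list(delta_r = box_summary(d$delta_r),
         abs_delta_r = box_summary(d$abs_delta_r),
         mean_abs_dr_over_sigma = mean(d$abs_delta_r) / sigma_r)
  })
  per_class_u <- lapply(split(du_rows, du_rows$class), function(d) {
    list(delta_u = box_summary(d$delta_u),
         abs_delta_u = box_summary(d$abs_delta_u),
         mean_abs_du_over_sigma = mean(d$abs_delta_u) / sigma_u)
  })
  rep <- list(wr2 = wr2, adp_scaling = list(q = fit$q,
                                            delta_u = matrix_to_u6(fit$delta_u),
                                            residual_rms = fit$residual_rms),
              bonds = dr, delta_u = du_rows, s12 = s12_vals,
              per_class_r = per_class, per_class_u = per_class_u)
  class(rep) <- "quality_report"
  rep
}

#' @export
print.quality_report <- function(x, ...) {
  if (is.finite(x$wr2)) cat(sprintf("wR2 = %.4f%%\n", 100 * x$wr2))
  cat(sprintf("ADP scaling q = %.4f\n", x$adp_scaling$q))
  cat("X-H bond-length differences (A):\n")
  print(x$bonds, row.names = FALSE, digits = 4)
  cat("S12 per H atom (%):\n")
  print(round(x$s12, 3))
  invisible(x)
}

#' Serialize a quality report
#'
#' Writes the report as JSON and the per-atom metrics as a flat CSV.
#'
#' @param report A \code{\link{quality_report}}.
#' @param json_path,csv_path Output paths (either may be \code{NULL}).
#' @return Invisibly, the report.
#' @export
write_quality_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- list(wr2 = report$wr2, adp_scaling = report$adp_scaling,
                    s12 = as.list(report$s12),
                    per_class_r = report$per_class_r,
                    per_class_u = report$per_class_u)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(csv_path)) {
    flat <- merge(report$bonds,
                  data.frame(from = names(report$s12), s12 = as.numeric(report$s12)),
                  by = "from", all.x = TRUE)
    utils::write.csv(flat, csv_path, row.names = FALSE)
  }
  invisible(report)
}
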