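#' Symmetry operation
#'
#' A crystallographic symmetry operation acting on fractional coordinates as
#' \code{x' = R x + t}.
#'
#' @param rotation 3x3 matrix of small rationals (usually 0, +1, -1) with
#'   determinant +1 or -1.
#' @param translation Length-3 vector of fractions; reduced modulo 1 into
#'   [0, 1).
#' @return Object of class \code{symop}.
#' @export
symop <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  d <- det(rotation)
  if (abs(abs(d) - 1) > 1e-10)
    stop("symmetry rotation must have determinant +1 or -1")
  translation <- as.numeric(translation) %% 1
  structure(list(R = rotation, t = translation), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("symop:", format_symop_xyz(x), "\n")
  invisible(x)
}

symop_identity <- function() symop(diag(3), c(0, 0, 0))

#' Parse an xyz-style symmetry operator string
#'
#' Accepts the CIF notation, e.g. \code{"-x, y+1/2, -z+1/2"}.
#'
#' @param s Character scalar.
#' @return A \code{\link{symop}}.
#' @export
parse_symop_xyz <- function(s) {
  parts <- strsplit(gsub("[ ']", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3) stop("symmetry operator must have three comma-separated parts: ", s)
  R <- matrix(0, 3, 3)
  tr <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr, fixed = TRUE)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (tm in terms) {
      sign <- 1
      if (startsWith(tm, "-")) { sign <- -1; tm <- substring(tm, 2) }
      axis <- regmatches(tm, regexpr("[xyz]", tm))
      if (length(axis) == 1) {
        coef <- gsub("[xyz]\\*?", "", tm)
        coef <- gsub("\\*", "", coef)
        val <- if (nzchar(coef)) eval_fraction(coef) else 1
        R[i, match(axis, c("x", "y", "z"))] <-
          R[i, match(axis, c("x", "y", "z"))] + sign * val
      } else {
        tr[i] <- tr[i] + sign * eval_fraction(tm)
      }
    }
  }
  symop(R, tr)
}

eval_fraction <- function(s) {
  if (grepl("/", s, fixed = TRUE)) {
    nd <- strsplit(s, "/", fixed = TRUE)[[1]]
    as.numeric(nd[1]) / as.numeric(nd[2])
  } else as.numeric(s)
}

#' Format a symmetry operator as an xyz string
#'
#' @param op A \code{\link{symop}}.
#' @return Character scalar such as \code{"-x, y+1/2, -z+1/2"}.
#' @export
format_symop_xyz <- function(op) {
  ax <- c("x", "y", "z")
  rows <- character(3)
  for (i in 1:3) {
    out <- ""
    for (j in 1:3) {
      cij <- op$R[i, j]
      if (abs(cij) < 1e-10) next
      sgn <- if (cij < 0) "-" else if (nzchar(out)) "+" else ""
      mag <- abs(cij)
      coef <- if (abs(mag - 1) < 1e-10) "" else frac_string(mag)
      out <- paste0(out, sgn, coef, ax[j])
    }
    ti <- op$t[i] %% 1
    if (ti > 1e-10) out <- paste0(out, "+", frac_string(ti))
    if (!nzchar(out)) out <- "0"
    rows[i] <- out
  }
  paste(rows, collapse = ", ")
}

frac_string <- function(v) {
  for (den in c(2, 3, 4, 6)) {
    num <- v * den
    if (abs(num - round(num)) < 1e-9) return(sprintf("%d/%d", as.integer(round(num)), den))
  }
  format(v)
}

apply_symop <- function(op, x) as.numeric(op$R %*% x) + op$t

# periodic fractional difference wrapped to [-0.5, 0.5)
wrap_diff <- function(d) d - round(d)

same_site <- function(x, y, tol = 1e-6) all(abs(wrap_diff(x - y)) < tol)

compose_symop <- function(a, b) symop(a$R %*% b$R, as.numeric(a$R %*% b$t) + a$t)

#' Check group closure of a symmetry list
#'
#' Verifies that the operator list contains the identity and is closed under
#' composition modulo lattice translations.
#'
#' @param symmetry List of \code{\link{symop}} objects.
#' @return \code{TRUE} invisibly; stops otherwise.
#' @export
check_symmetry_group <- function(symmetry) {
  has_id <- any(vapply(symmetry, function(op)
    all(abs(op$R - diag(3)) < 1e-10) && all(abs(wrap_diff(op$t)) < 1e-10), logical(1)))
  if (!has_id) stop("symmetry list must contain the identity operation")
  for (a in symmetry) for (b in symmetry) {
    ab <- compose_symop(a, b)
    found <- any(vapply(symmetry, function(op)
      all(abs(ab$R - op$R) < 1e-10) && all(abs(wrap_diff(ab$t - op$t)) < 1e-10), logical(1)))
    if (!found) stop("symmetry list is not closed under composition")
  }
  invisible(TRUE)
}

#' Site-symmetry operations of a position
#'
#' Operations of the group that map the position onto itself modulo lattice
#' translations.
#'
#' @param frac_pos Length-3 fractional position.
#' @param symmetry List of \code{\link{symop}} objects.
#' @param tol Fractional tolerance for coincidence (default 1e-6).
#' @return List of \code{symop}s (always contains the identity).
#' @export
site_symmetry_ops <- function(frac_pos, symmetry, tol = 1e-6) {
  Filter(function(op) same_site(apply_symop(op, frac_pos), frac_pos, tol), symmetry)
}

#' Expand a structure to P1
#'
#' Applies every symmetry operation to every atom of the asymmetric unit and
#' merges images that coincide on special positions.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param tol Fractional merge tolerance (default 1e-6).
#' @return List of image records, each with \code{atom} (the generated copy,
#'   position wrapped into [0,1)), \code{gen} (index of the generating atom)
#'   and \code{op} (the generating \code{\link{symop}}).
#' @export
expand_to_p1 <- function(structure, tol = 1e-6) {
  out <- list()
  n_ops <- length(structure$symmetry)
  for (ia in seq_along(structure$atoms)) {
    at <- structure$atoms[[ia]]
    seen <- list()
    for (op in structure$symmetry) {
      pos <- apply_symop(op, at$frac_pos) %% 1
      dup <- FALSE
      for (s in seen) if (same_site(pos, s, tol)) { dup <- TRUE; break }
      if (dup) next
      seen[[length(seen) + 1]] <- pos
      img <- at
      img$frac_pos <- pos
      out[[length(out) + 1]] <- list(atom = img, gen = ia, op = op)
    }
    mult <- length(seen)
    site <- length(site_symmetry_ops(at$frac_pos, structure$symmetry, tol))
    if (mult * site != n_ops)
      warning(sprintf("atom %s: multiplicity %d inconsistent with site order %d (group order %d)",
                      at$label, mult, site, n_ops))
  }
  out
}

# ---- representation matrices for site-constraint generation -----------------

# unique component index tuples and multiplicities of the third-order
# Gram-Charlier tensor C^{jkl} (10 components)
gc3_index_table <- function() {
  idx <- rbind(c(1,1,1), c(2,2,2), c(3,3,3),
               c(1,1,2), c(1,2,2), c(1,1,3), c(1,3,3), c(2,2,3), c(2,3,3),
               c(1,2,3))
  list(idx = idx, mult = c(1, 1, 1, 3, 3, 3, 3, 3, 3, 6))
}

# unique component index tuples and multiplicities of the fourth-order
# Gram-Charlier tensor D^{jklm} (15 components)
gc4_index_table <- function() {
  idx <- rbind(c(1,1,1,1), c(2,2,2,2), c(3,3,3,3),
               c(1,1,1,2), c(1,2,2,2), c(1,1,1,3), c(1,3,3,3),
               c(2,2,2,3), c(2,3,3,3),
               c(1,1,2,2), c(1,1,3,3), c(2,2,3,3),
               c(1,1,2,3), c(1,2,2,3), c(1,2,3,3))
  list(idx = idx, mult = c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12))
}

# full symmetric tensor array from unique components
gc_unique_to_full <- function(vals, tab) {
  rank <- ncol(tab$idx)
  arr <- array(0, rep(3, rank))
  for (r in seq_len(nrow(tab$idx))) {
    perms <- unique_permutations(tab$idx[r, ])
    for (p in seq_len(nrow(perms))) arr[matrix(perms[p, ], 1)] <- vals[r]
  }
  arr
}

gc_full_to_unique <- function(arr, tab) {
  apply(tab$idx, 1, function(ix) arr[matrix(ix, 1)])
}

unique_permutations <- function(v) {
  p <- perms_all(length(v))
  m <- t(apply(p, 1, function(o) v[o]))
  unique(m)
}

perms_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms_all(n - 1)
  out <- NULL
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# transform a contravariant symmetric tensor (given as unique components)
# by the fractional rotation W; returns unique components
gc_transform <- function(vals, tab, W) {
  rank <- ncol(tab$idx)
  arr <- gc_unique_to_full(vals, tab)
  new <- array(0, rep(3, rank))
  idx_grid <- as.matrix(expand.grid(rep(list(1:3), rank)))
  for (r in seq_len(nrow(idx_grid))) {
    ab <- idx_grid[r, ]
    acc <- 0
    for (s in seq_len(nrow(idx_grid))) {
      jk <- idx_grid[s, ]
      w <- 1
      for (q in seq_len(rank)) w <- w * W[ab[q], jk[q]]
      if (w != 0) acc <- acc + w * arr[matrix(jk, 1)]
    }
    new[matrix(ab, 1)] <- acc
  }
  gc_full_to_unique(new, tab)
}

# representation matrix of W acting on a parameter block
rep_matrix <- function(W, block = c("pos", "u6", "gc3", "gc4")) {
  block <- match.arg(block)
  if (block == "pos") return(W)
  if (block == "u6") {
    M <- matrix(0, 6, 6)
    for (cmp in 1:6) {
      e <- numeric(6); e[cmp] <- 1
      M[, cmp] <- matrix_to_u6(W %*% u6_to_matrix(e) %*% t(W))
    }
    return(M)
  }
  tab <- if (block == "gc3") gc3_index_table() else gc4_index_table()
  n <- nrow(tab$idx)
  M <- matrix(0, n, n)
  for (cmp in seq_len(n)) {
    e <- numeric(n); e[cmp] <- 1
    M[, cmp] <- gc_transform(e, tab, W)
  }
  M
}

# orthonormal basis of the subspace invariant under all reps (group average
# is idempotent; its column space is the fixed subspace, rank = trace)
invariant_basis <- function(reps) {
  n <- nrow(reps[[1]])
  P <- Reduce(`+`, reps) / length(reps)
  r <- round(sum(diag(P)))
  if (r <= 0) return(matrix(0, n, 0))
  sv <- svd(P)
  sv$u[, seq_len(r), drop = FALSE]
}

#' Special-position constraints for an atom
#'
#' Determines the site-symmetry group of the atom and returns linear
#' reparameterizations restricting each refinable block (position,
#' anisotropic U, third- and fourth-order Gram-Charlier tensors) to the
#' subspace invariant under the site symmetry. The constraints are applied
#' inside the optimizer as \code{full = offset + basis \%*\% free}.
#'
#' @param atom An \code{\link{atom}}.
#' @param symmetry List of \code{\link{symop}} objects.
#' @param tol Site-coincidence tolerance (fractional, default 1e-6).
#' @return List with elements \code{site_ops}, \code{pos} (list
#'   \code{offset}, \code{basis}), \code{u6}, \code{gc3}, \code{gc4}
#'   (each a basis matrix; position additionally has the snapped offset).
#'   On a general position every basis is a full identity.
#' @export
site_constraints <- function(atom, symmetry, tol = 1e-6) {
  ops <- site_symmetry_ops(atom$frac_pos, symmetry, tol)
  # snap the position onto the exact fixed point: average images, unwrapped
  imgs <- vapply(ops, function(op) {
    y <- apply_symop(op, atom$frac_pos)
    y - round(y - atom$frac_pos)
  }, numeric(3))
  x0 <- rowMeans(matrix(imgs, nrow = 3))
  Ws <- lapply(ops, `[[`, "R")
  list(site_ops = ops,
       pos = list(offset = x0,
                  basis = invariant_basis(lapply(Ws, rep_matrix, block = "pos"))),
       u6 = invariant_basis(lapply(Ws, rep_matrix, block = "u6")),
       gc3 = invariant_basis(lapply(Ws, rep_matrix, block = "gc3")),
       gc4 = invariant_basis(lapply(Ws, rep_matrix, block = "gc4")))
}
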