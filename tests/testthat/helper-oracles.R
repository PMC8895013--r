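# Independent oracles used across the suite. These deliberately avoid the
# package's internal helpers: tensors are expanded by sorting index tuples,
# overlaps are integrated on brute-force grids, and structure factors are
# summed directly from closed-form Gaussian transforms.

# full symmetric tensor lookup: value at (i,j,...) = unique component of the
# sorted tuple, matched against a reference ordering
gc3_unique_order <- rbind(c(1,1,1), c(2,2,2), c(3,3,3),
                          c(1,1,2), c(1,2,2), c(1,1,3), c(1,3,3),
                          c(2,2,3), c(2,3,3), c(1,2,3))
gc4_unique_order <- rbind(c(1,1,1,1), c(2,2,2,2), c(3,3,3,3),
                          c(1,1,1,2), c(1,2,2,2), c(1,1,1,3), c(1,3,3,3),
                          c(2,2,2,3), c(2,3,3,3),
                          c(1,1,2,2), c(1,1,3,3), c(2,2,3,3),
                          c(1,1,2,3), c(1,2,2,3), c(1,2,3,3))

tuple_component <- function(ix, order_tab, vals) {
  key <- paste(sort(ix), collapse = "")
  keys <- apply(order_tab, 1, function(r) paste(sort(r), collapse = ""))
  vals[match(key, keys)]
}

# brute-force 27/81-term Gram-Charlier multiplier
naive_gram_charlier <- function(h, gc3 = NULL, gc4 = NULL) {
  out <- 1 + 0i
  if (!is.null(gc3)) {
    s <- 0
    for (j in 1:3) for (k in 1:3) for (l in 1:3)
      s <- s + tuple_component(c(j, k, l), gc3_unique_order, gc3) *
        h[j] * h[k] * h[l]
    out <- out + (2i * pi)^3 / 6 * s
  }
  if (!is.null(gc4)) {
    s <- 0
    for (j in 1:3) for (k in 1:3) for (l in 1:3) for (m in 1:3)
      s <- s + tuple_component(c(j, k, l, m), gc4_unique_order, gc4) *
        h[j] * h[k] * h[l] * h[m]
    out <- out + (2i * pi)^4 / 24 * s
  }
  out
}

# brute-force numeric overlap of two trivariate Gaussian densities,
# 100 * (1 - integral sqrt(p1 p2))
numeric_s12 <- function(u1, u2, half_width = 0.8, spacing = 0.016) {
  xs <- seq(-half_width, half_width, by = spacing)
  g <- as.matrix(expand.grid(xs, xs, xs))
  dens <- function(u) {
    ui <- solve(u)
    (2 * pi)^(-1.5) * det(u)^(-0.5) *
      exp(-0.5 * rowSums((g %*% ui) * g))
  }
  ov <- sum(sqrt(dens(u1) * dens(u2))) * spacing^3
  100 * (1 - ov)
}

# random symmetric positive definite displacement matrix (angstrom^2 scale)
random_psd_u <- function(scale = 0.02) {
  m <- matrix(stats::rnorm(9, sd = scale), 3)
  s <- crossprod(m) + diag(3) * scale
  (s + t(s)) / 2
}

# closed-form spherical form factor of an element of the synthetic source
# (core + valence Gaussian shells), written out independently here
synthetic_ff_total <- function(element, s) {
  shells <- list(
    H = list(n = 1.0, alpha = 2.0),
    C = list(n = c(2.4, 1.6, 2), alpha = c(6.0, 1.5, 180)),
    N = list(n = c(3.0, 2.0, 2), alpha = c(8.0, 2.0, 250)),
    O = list(n = c(3.6, 2.4, 2), alpha = c(10.0, 2.5, 320))
  )[[element]]
  out <- 0
  for (i in seq_along(shells$n))
    out <- out + shells$n[i] * exp(-(4 * pi * s)^2 / (4 * shells$alpha[i]))
  out
}

# direct-summation structure factors from closed-form spherical form factors
direct_sum_fc <- function(structure, hkl) {
  s <- resolution(hkl, structure$cell)
  fc <- rep(0 + 0i, nrow(hkl))
  for (rec in expand_to_p1(structure)) {
    a <- rec$atom
    f <- synthetic_ff_total(a$element, s)
    fc <- fc + a$occupancy * f * debye_waller(hkl, a, structure$cell) *
      exp(2i * pi * as.numeric(hkl %*% a$frac_pos))
  }
  fc
}

# central finite-difference gradient with one Richardson extrapolation
# step (eliminates the O(h^2) truncation term)
fd_gradient <- function(fn, p, h = 1e-6) {
  central <- function(i, hh) {
    e <- numeric(length(p)); e[i] <- hh
    (fn(p + e) - fn(p - e)) / (2 * hh)
  }
  vapply(seq_along(p), function(i)
    (4 * central(i, h) - central(i, 2 * h)) / 3, numeric(1))
}

# perturb a structure: positions by exactly dist angstrom along unit
# directions that sum to zero (n-th roots of unity in a random plane), so
# the floating origin stays put; anisotropic U scaled by factor
perturb_structure <- function(st, dist = 0.05, u_factor = 1.2) {
  n <- length(st$atoms)
  b <- qr.Q(qr(matrix(stats::rnorm(9), 3)))[, 1:2]  # random orthonormal pair
  ang <- 2 * pi * (seq_len(n) - 1) / n + stats::runif(1, 0, 2 * pi)
  dirs <- cbind(cos(ang), sin(ang)) %*% t(b)
  for (i in seq_len(n)) {
    st$atoms[[i]]$frac_pos <- st$atoms[[i]]$frac_pos +
      cart_to_frac(dist * dirs[i, ], st$cell)
    if (!is.null(st$atoms[[i]]$uaniso))
      st$atoms[[i]]$uaniso <- st$atoms[[i]]$uaniso * u_factor
    else
      st$atoms[[i]]$uiso <- st$atoms[[i]]$uiso * u_factor
  }
  st
}

# largest positional error (angstrom) between two structures
max_position_error <- function(a, b) {
  G <- metric_tensors(a$cell)$G
  m <- 0
  for (i in seq_along(a$atoms)) {
    d <- wrap_diff(a$atoms[[i]]$frac_pos - b$atoms[[i]]$frac_pos)
    m <- max(m, sqrt(as.numeric(t(d) %*% G %*% d)))
  }
  m
}

wrap_diff <- function(d) d - round(d)
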